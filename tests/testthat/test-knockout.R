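fx <- fixture_library()

test_that("effective threshold is the smallest realizable lost fraction", {
  expect_identical(effective_threshold(5, 0.5), 0.6)
  expect_identical(effective_threshold(4, 0.5), 0.5)
  expect_identical(effective_threshold(1, 0.1), 1)
  expect_identical(effective_threshold(1, 1), 1)
  expect_error(effective_threshold(0, 0.5), "k must be")
  expect_error(model_config("SO", threshold = 0), "0 < T <= 1")
  expect_error(model_config("SO", threshold = 1.2), "0 < T <= 1")
  # guard against floating-point in T*k: T = 0.2, k = 5 is exactly realizable
  expect_identical(effective_threshold(5, 0.2), 0.2)
  expect_identical(effective_threshold(10, 0.3), 0.3)
  # always in [T, 1] and realizable
  for (k in 1:12) for (Tv in seq(0.1, 1, 0.1)) {
    te <- effective_threshold(k, Tv)
    expect_gte(te, Tv)
    expect_lte(te, 1)
    expect_equal(te * k, round(te * k))
  }
})

test_that("node-averaged effective threshold averages guilds as requested", {
  pm <- fx$perfect_matching
  expect_equal(node_average_effective_threshold(pm, 0.5), 1)
  all4 <- bipartite_network(matrix(1, 4, 4), weighted = FALSE)
  expect_equal(node_average_effective_threshold(all4, 0.5), 0.5)
  # mixed degrees {1, 5} in equal counts average (1.0 + 0.6)/2
  expect_equal(mean(effective_threshold(c(1, 5), 0.5)), 0.8)
  net <- fx$ac_like
  both <- node_average_effective_threshold(net, 0.5)
  anim <- node_average_effective_threshold(net, 0.5, guild = "animals")
  plts <- node_average_effective_threshold(net, 0.5, guild = "plants")
  A <- n_animals(net); P <- n_plants(net)
  expect_equal(both, (A * anim + P * plts) / (A + P))
})

test_that("robustness implements the normalized area and checks its contract", {
  expect_equal(robustness(c(4, 3, 2, 1, 0), 4, 4), 0.625)
  expect_equal(robustness(c(7, 0, 0, 0), 7, 3), 1 / 3)
  expect_equal(robustness(c(5, 5, 5, 0), 5, 3), 1)
  expect_error(robustness(c(4, 3, 0), 4, 3), "P \\+ 1")
  expect_error(robustness(c(4, 3, 4, 0), 4, 3), "non-increasing")
  expect_error(robustness(c(4, 3, 2, 1), 4, 3), "end at 0")
})

test_that("remove_plant applies the threshold rule in both modes", {
  # degree-1 pollinator dies with its only plant at any threshold
  star <- bipartite_network(matrix(1, 3, 1), weighted = FALSE)
  st <- extinction_state(star, model_config("SO", threshold = 0.1))
  out <- remove_plant(st, 1)
  expect_setequal(out$extinct_animals, 1:3)
  expect_error(remove_plant(out$state, 1), "already extinct")

  # binary degree-5 pollinator at T = 0.5 survives 2 lost edges, dies on the 3rd
  M <- matrix(0, 1, 5); M[1, ] <- 1
  net <- bipartite_network(M, weighted = FALSE)
  st <- extinction_state(net, model_config("SO", threshold = 0.5))
  st <- remove_plant(st, 1)$state
  out <- remove_plant(st, 2)
  expect_length(out$extinct_animals, 0)
  out <- remove_plant(out$state, 3)
  expect_equal(out$extinct_animals, 1L)

  # weighted pollinator with weights (9, 1): losing the weight-1 plant is
  # a 10% loss; losing the weight-9 plant crosses T = 0.5
  net <- bipartite_network(matrix(c(9, 1), 1, 2), weighted = TRUE)
  st <- extinction_state(net, model_config("SO", weighted = TRUE,
                                           threshold = 0.5))
  out <- remove_plant(st, 2)
  expect_length(out$extinct_animals, 0)
  st2 <- extinction_state(net, model_config("SO", weighted = TRUE,
                                            threshold = 0.5))
  out <- remove_plant(st2, 1)
  expect_equal(out$extinct_animals, 1L)
})

test_that("runs satisfy the universal contract for every model and mode", {
  for (net in c(property_fixtures(), fx["ac_like"])) {
    A <- n_animals(net); P <- n_plants(net)
    for (model in c("SO", "DA", "RW")) for (w in c(FALSE, TRUE)) {
      run <- run_model(net, model_config(model, weighted = w, seed = 11))
      expect_length(run$a_curve, P + 1)
      expect_equal(run$a_curve[1], A)
      expect_equal(run$a_curve[P + 1], 0)
      expect_true(all(diff(run$a_curve) <= 0))
      expect_setequal(run$plant_sequence, seq_len(P))
      expect_setequal(unname(run$ranks), seq_len(P))
      expect_equal(unname(run$ranks[run$plant_sequence]), seq_len(P))
      expect_gte(run$R, 1 / P)
      expect_lt(run$R, 1)
      expect_true(run$trigger_flags[1])
      if (model == "SO") expect_true(all(run$trigger_flags))
    }
  }
})

test_that("identical (network, config, seed) gives bit-identical runs", {
  for (model in c("SO", "DA", "RW")) {
    r1 <- run_model(fx$ac_like, model_config(model, seed = 77))
    r2 <- run_model(fx$ac_like, model_config(model, seed = 77))
    expect_identical(r1, r2)
  }
})

test_that("at T = 1, binary and weighted SO coincide and DA reduces to SO", {
  for (seed in c(3, 14, 159)) {
    for (net in list(property_fixtures()[[4]], fx$ac_like)) {
      bso <- run_model(net, model_config("SO", weighted = FALSE,
                                         threshold = 1, seed = seed))
      wso <- run_model(net, model_config("SO", weighted = TRUE,
                                         threshold = 1, seed = seed))
      expect_equal(bso$plant_sequence, wso$plant_sequence)
      expect_equal(bso$a_curve, wso$a_curve)
      expect_equal(bso$R, wso$R)
      da <- run_model(net, model_config("DA", weighted = FALSE,
                                        threshold = 1, seed = seed))
      expect_equal(da$plant_sequence, bso$plant_sequence)
      expect_equal(da$a_curve, bso$a_curve)
      expect_true(all(da$trigger_flags))
    }
  }
})

test_that("the engine agrees with step-by-step remove_plant replay", {
  for (net in property_fixtures()) for (w in c(FALSE, TRUE)) {
    cfg <- model_config("SO", weighted = w, seed = 5)
    run <- run_model(net, cfg)
    st <- extinction_state(net, cfg)
    a <- n_animals(net)
    curve <- c(a)
    for (e in run$plant_sequence) {
      out <- remove_plant(st, e)
      st <- out$state
      a <- a - length(out$extinct_animals)
      curve <- c(curve, a)
    }
    expect_equal(curve, run$a_curve)
  }
})

test_that("DA avalanches propagate through shared pollinators", {
  # two plants, each with a private degree-1 pollinator, sharing a third:
  # any trigger kills its private and the shared pollinator, pushing the
  # other plant over T = 0.5, so the avalanche needs exactly one trigger
  M <- rbind(c(1, 0), c(1, 1), c(0, 1))
  net <- bipartite_network(M, weighted = FALSE)
  for (seed in 1:10) {
    run <- run_model(net, model_config("DA", seed = seed))
    expect_equal(sum(run$trigger_flags), 1L)
    expect_equal(run$a_curve, c(3, 1, 0))
  }
})

test_that("random walk follows shared pollinators and restarts when stranded", {
  # perfect matching: no shared pollinators, every step is a restart
  run <- run_model(fx$perfect_matching, model_config("RW", seed = 1))
  expect_true(all(run$trigger_flags))

  # two components: non-trigger steps never cross the component boundary
  comp <- c(1, 1, 2, 2)
  for (seed in 1:20) {
    run <- run_model(fx$two_component, model_config("RW", seed = seed))
    s <- run$plant_sequence
    for (i in 2:length(s))
      if (!run$trigger_flags[i])
        expect_equal(comp[s[i]], comp[s[i - 1]])
  }
})

test_that("walk victims are chosen proportional to shared pollinator counts", {
  # plant 1 shares 2 pollinators with plant 2 and 1 with plant 3:
  # from trigger 1 the next victim is plant 2 with probability 2/3
  M <- rbind(c(1, 1, 0), c(1, 1, 0), c(1, 0, 1))
  net <- bipartite_network(M, weighted = FALSE)
  hits <- 0L; total <- 0L
  for (i in 1:30000) {
    run <- run_model(net, model_config("RW", seed = 50000L + i))
    if (run$plant_sequence[1] == 1 && !run$trigger_flags[2]) {
      total <- total + 1L
      if (run$plant_sequence[2] == 2) hits <- hits + 1L
    }
  }
  expect_gt(total, 5000)
  p_hat <- hits / total
  se <- sqrt(2 / 9 / total)
  expect_lt(abs(p_hat - 2 / 3), 3 * se)
})

test_that("shared_pollinator_matrix matches the brute-force projection", {
  id <- extinction_state(bipartite_network(diag(3)), model_config("SO"))
  expect_true(all(shared_pollinator_matrix(id) == 0))
  one <- extinction_state(bipartite_network(matrix(1, 1, 4)),
                          model_config("SO"))
  F_ <- shared_pollinator_matrix(one)
  expect_true(all(F_[upper.tri(F_)] == 1))
  expect_true(all(diag(F_) == 0))
  # block structure across components
  Ftc <- shared_pollinator_matrix(
    extinction_state(fx$two_component, model_config("SO")))
  expect_true(all(Ftc[1:2, 3:4] == 0))
  for (net in property_fixtures()) {
    st <- extinction_state(net, model_config("SO"))
    st <- remove_plant(st, 1)$state   # also test on a reduced state
    expect_equal(unname(shared_pollinator_matrix(st)),
                 unname(oracle_shared_matrix(st$C)))
  }
})

test_that("ordered runs bracket robustness and replay recorded sequences", {
  pm <- fx$perfect_matching
  cfg <- model_config("SO")
  inc <- run_ordered(pm, "increasing_degree", cfg)
  dec <- run_ordered(pm, "decreasing_degree", cfg)
  expect_equal(inc$R, 0.625)
  expect_equal(dec$R, 0.625)

  ac <- fx$ac_like
  inc <- run_ordered(ac, "increasing_degree", cfg)
  dec <- run_ordered(ac, "decreasing_degree", cfg)
  expect_gt(inc$R, dec$R)

  rec <- run_model(ac, model_config("SO", seed = 21))
  replay <- run_ordered(ac, rec$plant_sequence, cfg)
  expect_equal(replay$R, rec$R)
  expect_equal(replay$a_curve, rec$a_curve)

  expect_error(run_ordered(ac, c(1, 1, 2), cfg), "permutation")
})

test_that("the engine matches the naive oracle on explicit orders", {
  for (net in property_fixtures()) for (w in c(FALSE, TRUE)) {
    P <- n_plants(net)
    set.seed(31 + P)
    for (i in 1:3) {
      ord <- sample.int(P)
      run <- run_ordered(net, ord, model_config("SO", weighted = w))
      expect_equal(run$a_curve,
                   oracle_so_curve(net$M, ord, 0.5, weighted = w))
    }
  }
})
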