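test_that("elementary-update frequencies match exhaustive enumeration on 2x2", {
  grid <- matrix(c(1L, 0L, 2L, 3L), 2, 2) # A, vacant | B, C
  rates <- paper_rates()
  # pulse-elevated death on A, baseline on B and C
  d_eff <- c(0.3, 0.1, 0.1)
  expected <- enumerate_2x2(grid, p = 0.2, r = 0.4, d_eff = d_eff)
  expect_equal(sum(expected), 1, tolerance = 1e-12)

  st <- structure(list(grid = grid,
                       counts = c(vacant = 1, a = 1, b = 1, c = 1), t = 5),
                  class = "lattice_state")
  pulse <- pulse_spec(0.2, tau = 15, onset = 0, target = "A")
  n <- 2e5
  keys <- vapply(seq_len(n), function(k) {
    out <- mc_elementary_update(st, rates, pulse, n_updates = 1,
                                seed = derive_seed(4242, 0, 0, k))
    paste(out$grid, collapse = "")
  }, character(1))
  expect_true(all(keys %in% names(expected))) # no impossible moves
  emp <- table(factor(keys, levels = names(expected))) / n
  sigma <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(as.numeric(emp) - expected) <= 4 * sigma + 1e-12))
})

test_that("lattice initialisation reproduces requested densities", {
  # degenerate distribution fills every site
  st <- init_lattice(10, densities(1, 0, 0), seed = 1)
  expect_equal(st$counts[["a"]], 100)
  # counts always total L^2
  st2 <- init_lattice(17, densities(0.2, 0.3, 0.1), seed = 3)
  expect_equal(sum(st2$counts), 17^2)
  expect_equal(as.numeric(st2$counts),
               tabulate(as.integer(st2$grid) + 1L, 4L)) # counts match grid
  # binomial moments at L = 200: each species within 4 sd of 12000
  st3 <- init_lattice(200, densities(0.3, 0.3, 0.3), seed = 7)
  sd_bin <- sqrt(40000 * 0.3 * 0.7)
  for (sp in c("a", "b", "c")) {
    expect_lt(abs(st3$counts[[sp]] - 12000), 4 * sd_bin)
  }
  # reproducible for a fixed seed
  expect_identical(init_lattice(20, densities(0.3, 0.3, 0.3), seed = 5)$grid,
                   init_lattice(20, densities(0.3, 0.3, 0.3), seed = 5)$grid)
})

test_that("elementary events implement death, reproduction and predation", {
  rates_death <- rate_set_symmetric(0.2, 0.4, 1) # certain death
  st <- init_lattice(3, densities(1, 0, 0), seed = 1)
  out <- mc_elementary_update(st, rates_death, seed = 1)
  expect_equal(out$counts[["a"]], 8)
  expect_equal(out$counts[["vacant"]], 1)

  # lone occupant with certain reproduction and no death colonises a vacancy
  grid <- matrix(0L, 2, 2); grid[1, 1] <- 1L
  st <- structure(list(grid = grid, counts = c(vacant = 3, a = 1, b = 0, c = 0),
                       t = 0), class = "lattice_state")
  out <- mc_elementary_update(st, rate_set_symmetric(0.2, 1, 0), seed = 2)
  expect_equal(out$counts[["a"]], 2)

  # predation with p = 1: first change converts one B site to vacancy and
  # leaves the predator count untouched
  grid <- matrix(2L, 3, 3); grid[2, 2] <- 1L
  st <- structure(list(grid = grid, counts = c(vacant = 0, a = 1, b = 8, c = 0),
                       t = 0), class = "lattice_state")
  k <- 0
  repeat {
    k <- k + 1
    out <- mc_elementary_update(st, rate_set_symmetric(1, 0.4, 0), seed = k)
    if (!identical(out$grid, st$grid)) break
  }
  expect_equal(out$counts[["a"]], 1)
  expect_equal(out$counts[["b"]], 7)
  expect_equal(out$counts[["vacant"]], 1)

  expect_error(
    mc_elementary_update(init_lattice(4, densities(0, 0, 0), seed = 1),
                         paper_rates()),
    "vacant")
})

test_that("site counts are conserved through arbitrary update sequences", {
  st <- init_lattice(12, densities(0.25, 0.25, 0.25), seed = 11)
  out <- mc_elementary_update(st, paper_rates(), pulse_spec(0.2, 10),
                              n_updates = 2000, seed = 13)
  expect_equal(sum(out$counts), 144)
  expect_equal(as.numeric(out$counts), tabulate(as.integer(out$grid) + 1L, 4L))
})

test_that("a lone species fluctuates near the single-species balance", {
  # mean-field balance r rho_v = d gives rho = (r - d) / r = 0.75; on the
  # lattice, clustering biases the chosen neighbour towards occupied sites,
  # so the stationary density sits a few percent below that
  cfg <- simulation_config("lattice", L = 50, t_max = 300, seed = 17,
                           init = densities(0, 0.5, 0))
  res <- run_lattice(cfg, early_stop = FALSE)
  tr <- res$trajectory
  m <- mean(tr$rho_b[tr$t > 50])
  expect_gt(m, 0.65)
  expect_lt(m, 0.75)
  expect_true(all(tr$rho_a == 0))
})

test_that("an isolated individual without reproduction goes extinct", {
  grid <- matrix(0L, 5, 5); grid[3, 3] <- 1L
  cfg <- simulation_config("lattice", L = 5, t_max = 500, seed = 23,
                           rates = rate_set_symmetric(0.2, 0, 0.1),
                           init = densities(1 / 25, 0, 0))
  # bypass random init to place exactly one individual
  st <- structure(list(grid = grid, counts = c(vacant = 24, a = 1, b = 0,
                                               c = 0), t = 0),
                  class = "lattice_state")
  raw <- rpspulse:::lattice_run_cpp(st$grid, 0.2, 0, 0.1, 0, 0, 0, 1,
                                    500L, 0L, 31, TRUE)
  expect_equal(sum(raw$counts[2:4]), 0)
  expect_true(raw$stopped_early)
})

test_that("relabelling species together with the pulse target is symmetric", {
  outcomes <- list()
  for (target in c("A", "B", "C")) {
    labels <- character(60)
    for (k in 1:60) {
      cfg <- simulation_config("lattice", L = 40, t_max = 300,
                               pulse = pulse_spec(0.2, 20, target = target),
                               seed = derive_seed(900, match(target, LETTERS),
                                                  0, k))
      labels[k] <- as.character(run_lattice(cfg)$outcome$label)
    }
    # rotate survivor labels into the pulsed species' frame
    rot <- c("A", "B", "C")
    shift <- match(target, rot) - 1
    frame <- c(coexistence = "coexistence", all_extinct = "all_extinct",
               setNames(paste0("rel_", 0:2),
                        paste0("only_", rot[(shift + 0:2) %% 3 + 1])))
    outcomes[[target]] <- frame[labels]
  }
  lev <- unique(unlist(outcomes))
  tab <- sapply(outcomes, function(x) table(factor(x, levels = lev)))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  set.seed(1)
  p <- chisq.test(tab, simulate.p.value = TRUE, B = 2000)$p.value
  expect_gt(p, 0.01)
})
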