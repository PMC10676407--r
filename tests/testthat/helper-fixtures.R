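# study conditions shared across tests
paper_rates <- function() rate_set_symmetric(p = 0.2, r = 0.4, d = 0.1)

paper_fp <- function() interior_fixed_point(paper_rates())

# share (%) of decided single-survivor runs won by each species
survivor_shares <- function(tab) {
  decided <- tab$label %in% c("only_A", "only_B", "only_C")
  counts <- table(factor(tab$label[decided],
                         levels = c("only_A", "only_B", "only_C")))
  list(counts = as.numeric(counts), n_decided = sum(decided),
       shares = as.numeric(counts) / sum(decided) * 100)
}

# build a survival_map object from a bare probability table, for testing
# map-consumers without paying for simulations
fake_survival_map <- function(delta_d, tau, p_only_b, n_runs = 100,
                              engine = "sde") {
  cells <- expand.grid(delta_d = delta_d, tau = tau,
                       outcome = c("coexistence", "only_A", "only_B",
                                   "only_C", "all_extinct"),
                       stringsAsFactors = FALSE)
  cells$probability <- 0
  for (i in seq_along(delta_d)) {
    for (j in seq_along(tau)) {
      pb <- p_only_b[i, j]
      sel_b <- cells$delta_d == delta_d[i] & cells$tau == tau[j]
      cells$probability[sel_b & cells$outcome == "only_B"] <- pb
      cells$probability[sel_b & cells$outcome == "coexistence"] <- 1 - pb
    }
  }
  cells$n_runs <- n_runs
  structure(list(cells = cells, delta_d = delta_d, tau = tau,
                 n_runs = n_runs, engine = engine, base_seed = 0,
                 config = list()),
            class = "survival_map")
}

# exhaustive next-configuration distribution for one elementary event on a
# 2 x 2 periodic lattice, written independently of the engine: site choice
# (uniform over occupied) x death branch x neighbour direction x action
enumerate_2x2 <- function(grid, p, r, d_eff) {
  stopifnot(all(dim(grid) == c(2, 2)))
  prey_of <- c(2, 3, 1)
  occupied <- which(grid != 0)
  probs <- new.env()
  add <- function(g, pr) {
    key <- paste(g, collapse = "")
    probs[[key]] <- (if (is.null(probs[[key]])) 0 else probs[[key]]) + pr
  }
  for (idx in occupied) {
    p_site <- 1 / length(occupied)
    s <- grid[idx]
    # death branch
    g <- grid; g[idx] <- 0
    add(g, p_site * d_eff[s])
    p_live <- p_site * (1 - d_eff[s])
    # on a 2 x 2 torus the two vertical directions hit the same cell, as do
    # the two horizontal ones
    row <- (idx - 1) %% 2; col <- (idx - 1) %/% 2
    vert <- (1 - row) + col * 2 + 1
    horiz <- row + (1 - col) * 2 + 1
    for (nb in c(vert, horiz)) {
      p_nb <- p_live / 2
      ns <- grid[nb]
      if (ns == 0) {
        g <- grid; g[nb] <- s
        add(g, p_nb * r)
        add(grid, p_nb * (1 - r))
      } else if (ns == prey_of[s]) {
        g <- grid; g[nb] <- 0
        add(g, p_nb * p)
        add(grid, p_nb * (1 - p))
      } else {
        add(grid, p_nb)
      }
    }
  }
  out <- unlist(as.list(probs))
  out[order(names(out))]
}
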