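# Independent oracles used across the suite.

# Largest positive real root of the steady-state balance, via the closed-form
# cubic: -mu_A*c*A^3 + (G_A + rho_A*c)*A^2 - mu_A*k*A + rho_A*k = 0,
# c = G_H/mu_H (polynomial solve, independent of the package's bracketed
# root finder).
steady_state_oracle <- function(p) {
  cc <- p$G_H / p$mu_H
  coefs <- c(p$rho_A * p$k, -p$mu_A * p$k, p$G_A + p$rho_A * cc,
             -p$mu_A * cc)
  r <- polyroot(coefs)
  re <- Re(r[abs(Im(r)) < 1e-8 * (1 + Mod(r))])
  re <- re[re > 0]
  if (!length(re)) return(NULL)
  A <- max(re)
  list(A_star = A, H_star = cc * A^2)
}

# Connected-component labelling by iterative minimum-label propagation —
# an algorithm independent of the package's BFS.
flood_fill_oracle <- function(mask, connectivity = 4, periodic = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[mask == 0] <- 0L
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  shift <- function(M, dr, dc) {
    if (periodic) {
      ri <- ((seq_len(nr) - 1 + dr) %% nr) + 1
      ci <- ((seq_len(nc) - 1 + dc) %% nc) + 1
      M[ri, ci, drop = FALSE]
    } else {
      out <- matrix(Inf, nr, nc)
      rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
      ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
      out[ok_r, ok_c] <- M[rs[ok_r], cs[ok_c], drop = FALSE]
      out
    }
  }
  repeat {
    lab2 <- lab
    for (off in offs) {
      nb <- shift(lab, off[1], off[2])
      nb[!is.finite(nb) | nb == 0] <- Inf
      cand <- pmin(lab2, nb)
      lab2[mask == 1 & cand > 0 & is.finite(cand)] <-
        cand[mask == 1 & cand > 0 & is.finite(cand)]
    }
    if (identical(lab2, lab)) break
    lab <- lab2
  }
  lab
}

# relabel a label map by order of first occurrence (column-major), so maps
# from different algorithms can be compared directly
normalize_labels <- function(lab) {
  v <- as.vector(lab)
  fg <- v[v != 0]
  key <- match(v, unique(fg[fg != 0]))
  key[v == 0] <- 0L
  matrix(as.integer(key), nrow(lab), ncol(lab))
}

# short full-physics run used by interface tests (small grid, capped time)
quick_sim <- function(scen = "standard", n = 32, seed = 1, t_end = 2000, ...) {
  simulate_pattern(scen, grid = sim_grid(n), seed = seed,
                   control = solver_control(t_end = t_end), ...)
}
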