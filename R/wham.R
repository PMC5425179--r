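#' Collect energy (and Q) samples from constant-temperature runs
#'
#' @param trajectories list of `kc_trajectory` from equilibrium runs at
#'   different temperatures (several runs may share a temperature).
#' @param topology optional `native_topology`; when supplied, per-frame Q
#'   values are attached so that free-energy profiles F(Q) can be computed.
#' @param discard_frac fraction of initial frames discarded as
#'   equilibration (default 0.1).
#' @return object of class `histogram_set`: per run `temperature`,
#'   `E` (potential energy samples) and optionally `Q`.
#' @export
histogram_set <- function(trajectories, topology = NULL, discard_frac = 0.1) {
  runs <- lapply(trajectories, function(tr) {
    nf <- n_frames(tr)
    keep <- seq.int(max(2L, floor(discard_frac * nf) + 1L), nf)
    list(temperature = tr$config$temperature,
         E = tr$epot[keep],
         Q = if (!is.null(topology)) series_q(tr, topology)[keep] else NULL)
  })
  structure(list(runs = runs), class = "histogram_set")
}

#' Weighted histogram analysis over energy
#'
#' Standard self-consistent WHAM: runs at temperatures `T_k` contribute
#' energy histograms `n_k(E)`; iteration alternates between the density of
#' states
#' `Omega(E) = sum_k n_k(E) / sum_k N_k exp(f_k - E / kB T_k)`
#' and the per-run shifts `exp(-f_k) = sum_E Omega(E) exp(-E / kB T_k)`
#' until the largest relative change in `f_k` drops below `tol`. Energy
#' bins use the Freedman-Diaconis width on the pooled samples.
#'
#' @param h [histogram_set()]
#' @param tol convergence tolerance on the shifts (default 1e-7).
#' @param max_iter iteration cap (default 10000).
#' @param n_bins optional explicit bin count (overrides Freedman-Diaconis).
#' @return object of class `wham_result`: `f` (per-run shifts, first run
#'   0), `E_mid`, `log_omega` (log density of states), `temperatures`,
#'   `converged`, `iterations`, plus the per-sample data for reweighting.
#' @export
wham_solve <- function(h, tol = 1e-7, max_iter = 10000L, n_bins = NULL) {
  stopifnot(inherits(h, "histogram_set"))
  runs <- h$runs
  K <- length(runs)
  if (K == 0L) stop("empty histogram set")
  if (any(vapply(runs, function(r) length(r$E), numeric(1)) < 100)) {
    warning("some runs have fewer than 100 samples")
  }
  E_all <- unlist(lapply(runs, `[[`, "E"))
  Tk <- vapply(runs, `[[`, numeric(1), "temperature")
  Nk <- vapply(runs, function(r) length(r$E), numeric(1))

  if (is.null(n_bins)) {
    iqr <- stats::IQR(E_all)
    bw <- if (iqr > 0) 2 * iqr / length(E_all)^(1 / 3) else diff(range(E_all)) / 50
    n_bins <- max(20L, min(400L, ceiling(diff(range(E_all)) / max(bw, 1e-12))))
  }
  rng <- range(E_all)
  pad <- 1e-9 * max(1, abs(rng[2] - rng[1]))
  edges <- seq(rng[1] - pad, rng[2] + pad, length.out = n_bins + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2

  counts <- vapply(runs, function(r) {
    tabulate(findInterval(r$E, edges, all.inside = TRUE), nbins = n_bins)
  }, numeric(n_bins))
  counts <- matrix(counts, nrow = n_bins)

  ## overlap warning between adjacent temperatures
  if (K > 1L) {
    ord <- order(Tk)
    for (a in seq_len(K - 1L)) {
      shared <- sum(counts[, ord[a]] > 0 & counts[, ord[a + 1L]] > 0)
      if (shared < 5) {
        warning(sprintf("insufficient overlap between T = %g and T = %g (%d shared bins)",
                        Tk[ord[a]], Tk[ord[a + 1L]], shared))
      }
    }
  }

  n_tot <- rowSums(counts)
  beta <- 1 / (kB * Tk)
  ## log-space iteration for numerical safety
  f <- rep(0, K)  # f_k = -log Z_k up to a constant, in the WHAM sense
  bE <- outer(mid, beta)  # n_bins x K: E * beta_k
  logN <- log(Nk)
  iter <- 0L
  converged <- FALSE
  occupied <- n_tot > 0
  while (iter < max_iter) {
    iter <- iter + 1L
    ## log denominator per bin: logsumexp_k( logN_k + f_k - beta_k E )
    A <- sweep(-bE, 2, logN + f, `+`)
    amax <- apply(A, 1, max)
    log_den <- amax + log(rowSums(exp(A - amax)))
    log_omega <- ifelse(occupied, log(n_tot) - log_den, -Inf)
    ## new f_k = -log sum_E omega(E) exp(-beta_k E)
    B <- log_omega - bE          # n_bins x K
    B <- B[occupied, , drop = FALSE]
    bmax <- apply(B, 2, max)
    f_new <- -(bmax + log(colSums(exp(sweep(B, 2, bmax)))))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f) / pmax(abs(f_new), 1))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("WHAM not converged after ", max_iter, " iterations")

  A <- sweep(-bE, 2, logN + f, `+`)
  amax <- apply(A, 1, max)
  log_den <- amax + log(rowSums(exp(A - amax)))
  log_omega <- ifelse(occupied, log(n_tot) - log_den, -Inf)
  lmax <- max(log_omega[occupied])
  log_omega <- log_omega - lmax

  ## per-sample log weights (2-D reweighting route): for sample s from any
  ## run, w(s; T) ∝ exp(-beta E_s) / sum_k N_k exp(f_k - beta_k E_s)
  Q_all <- if (!is.null(runs[[1]]$Q)) unlist(lapply(runs, `[[`, "Q")) else NULL
  As <- outer(E_all, -beta)
  As <- sweep(As, 2, logN + f, `+`)
  asm <- apply(As, 1, max)
  log_den_s <- asm + log(rowSums(exp(As - asm)))

  structure(
    list(f = f, temperatures = Tk, n_samples = Nk,
         E_mid = mid, log_omega = log_omega, occupied = occupied,
         E_samples = E_all, Q_samples = Q_all, log_den_samples = log_den_s,
         converged = converged, iterations = iter, tol = tol),
    class = "wham_result")
}

#' @export
print.wham_result <- function(x, ...) {
  cat(sprintf("wham_result: %d runs (T %g..%g), %d energy bins, %s in %d iterations\n",
              length(x$f), min(x$temperatures), max(x$temperatures),
              length(x$E_mid),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

wham_moments <- function(res, TT) {
  beta <- 1 / (kB * TT)
  lw <- res$log_omega - beta * res$E_mid
  lw[!res$occupied] <- -Inf
  m <- max(lw)
  w <- exp(lw - m)
  Z <- sum(w)
  E1 <- sum(w * res$E_mid) / Z
  E2 <- sum(w * res$E_mid^2) / Z
  c(E1 = E1, E2 = E2)
}

#' Heat capacity from a WHAM density of states
#'
#' `C_v(T) = (<E^2> - <E>^2) / (kB T^2)` (with the energy variance from
#' the reweighted density of states). Temperatures more than 20% outside
#' the sampled span are flagged as extrapolation.
#'
#' @param res [wham_solve()] result.
#' @param T_grid temperatures to evaluate (default: 200 points across the
#'   sampled span).
#' @return data.frame `T`, `Cv`, `extrapolated`.
#' @export
heat_capacity <- function(res, T_grid = NULL) {
  if (is.null(T_grid)) {
    T_grid <- seq(min(res$temperatures), max(res$temperatures),
                  length.out = 200L)
  }
  mm <- t(vapply(T_grid, function(TT) wham_moments(res, TT), numeric(2)))
  cv <- (mm[, 2] - mm[, 1]^2) / (kB * T_grid^2)
  lo <- min(res$temperatures) * 0.8
  hi <- max(res$temperatures) * 1.2
  data.frame(T = T_grid, Cv = pmax(cv, 0),
             extrapolated = T_grid < lo | T_grid > hi)
}

#' Folding temperature from the heat-capacity peak
#'
#' The folding temperature is the position of the C_v peak, refined by a
#' 3-point quadratic fit around the grid maximum.
#'
#' @param cv data.frame from [heat_capacity()] (`T`, `Cv`).
#' @return T_f (reduced temperature units).
#' @export
locate_tf <- function(cv) {
  i <- which.max(cv$Cv)
  if (i == 1L || i == nrow(cv)) stop("T_f outside sampled range")
  x <- cv$T[(i - 1):(i + 1)]
  y <- cv$Cv[(i - 1):(i + 1)]
  d2 <- (y[3] - 2 * y[2] + y[1])
  if (d2 >= 0) return(cv$T[i])
  x[2] + 0.5 * (x[2] - x[1]) * (y[1] - y[3]) / d2
}

#' Free-energy profile F(Q; T) by sample reweighting
#'
#' 2-D WHAM via per-sample weights: every sample (from every run) carries
#' the converged WHAM weight at the target temperature; F(Q) is
#' `-kB T log P(Q)` from the weighted Q histogram, minimum shifted to 0.
#' Empty Q bins stay absent (`NA`).
#'
#' @param res [wham_solve()] result built from a [histogram_set()] with Q.
#' @param TT target reduced temperature.
#' @param bin_width Q bin width (default 0.05).
#' @return data.frame of class `fq_profile`: `Q_mid`, `F`, `weight`, plus
#'   attributes `barrier` (list `Q`, `height`) when a barrier exists.
#' @export
free_energy_profile <- function(res, TT, bin_width = 0.05) {
  if (is.null(res$Q_samples)) stop("histogram set carried no Q samples")
  beta <- 1 / (kB * TT)
  lw <- -beta * res$E_samples - res$log_den_samples
  lw <- lw - max(lw)
  w <- exp(lw)
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  bin <- findInterval(pmin(res$Q_samples, 1 - 1e-12), edges,
                      all.inside = TRUE)
  nb <- length(edges) - 1L
  wsum <- vapply(seq_len(nb), function(b) sum(w[bin == b]), numeric(1))
  cnt <- tabulate(bin, nbins = nb)
  P <- ifelse(cnt > 0 & wsum > 0, wsum / sum(wsum), NA)
  FQ <- -kB * TT * log(P)
  FQ <- FQ - min(FQ, na.rm = TRUE)
  out <- data.frame(Q_mid = (edges[-length(edges)] + edges[-1]) / 2,
                    F = FQ, weight = P, n_samples = cnt)
  attr(out, "barrier") <- locate_barrier(out)
  class(out) <- c("fq_profile", "data.frame")
  out
}

## highest interior maximum between the two lowest minima of F(Q)
locate_barrier <- function(fq) {
  occ <- which(!is.na(fq$F))
  if (length(occ) < 3L) return(list(Q = NA_real_, height = 0))
  q <- fq$Q_mid[occ]; f <- fq$F[occ]
  n <- length(f)
  is_min <- vapply(seq_len(n), function(i) {
    (i == 1 || f[i] <= f[i - 1]) && (i == n || f[i] <= f[i + 1])
  }, logical(1))
  mins <- which(is_min)
  if (length(mins) < 2L) return(list(Q = NA_real_, height = 0))
  ord <- mins[order(f[mins])][1:2]
  lo <- min(ord); hi <- max(ord)
  if (hi - lo < 2L) return(list(Q = NA_real_, height = 0))
  seg <- (lo + 1L):(hi - 1L)
  ib <- seg[which.max(f[seg])]
  ## barrier height relative to the shallower of the two basins
  list(Q = q[ib], height = f[ib] - max(f[lo], f[hi]))
}

#' Barrier position and height of an F(Q) profile
#' @param fq [free_energy_profile()] result.
#' @return list `Q`, `height` (epsilon).
#' @export
fq_barrier <- function(fq) attr(fq, "barrier")
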