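#' Detection probability of an n-mer: simple model
#'
#' A complex of `n` identical subunits, each carrying one indicator
#' fluorophore detected independently with recall rate `p`, is detected when
#' at least one indicator is seen:
#'
#'   P_d(n) = 1 - (1 - p)^n
#'
#' @param n Oligomeric state(s), positive integer.
#' @param p Indicator recall rate in `[0, 1]`.
#' @return Detection probability, recycled over `n` and `p`.
#' @examples
#' pd_simple(1:4, 0.12)
#' @export
pd_simple <- function(n, p) {
  if (any(n < 1) || any(n != round(n)))
    abort("`n` must be a positive integer.", class = "dcc_domain_error")
  if (any(p < 0) || any(p > 1))
    abort("`p` must be in [0, 1].", class = "dcc_domain_error")
  1 - (1 - p)^n
}

#' Detection probability of an n-mer: double-loss model
#'
#' Extends the simple model with a double-loss factor `m`: the probability
#' that a subunit loses both its marker and indicator fluorophore at once
#' (e.g. truncation within the linker), which breaks the independence of the
#' two channels. Conditioning on the complex being marker-visible (at least
#' one subunit not double-lost),
#'
#'   P_d(n) = sum_{k=1}^{n} C(n,k) (1-m)^k m^(n-k) / (1 - m^n) * (1 - (1-p)^k)
#'
#' where k runs over the number of subunits that retained their fluorophores.
#' `m = 0` recovers the simple model; `m = 1` is degenerate (no complex is
#' ever visible).
#'
#' @param n Oligomeric state(s), positive integer.
#' @param p Indicator recall rate in `[0, 1]`.
#' @param m Double-loss probability in `[0, 1)`.
#' @return Detection probability, recycled over the inputs.
#' @examples
#' pd_modified(2, 0.17, 0.30) # 0.2460
#' @export
pd_modified <- function(n, p, m) {
  if (any(n < 1) || any(n != round(n)))
    abort("`n` must be a positive integer.", class = "dcc_domain_error")
  if (any(p < 0) || any(p > 1) || any(m < 0))
    abort("`p` and `m` must be probabilities.", class = "dcc_domain_error")
  if (any(m >= 1))
    abort("`m` = 1 is degenerate: no complex is ever marker-visible.",
          class = "dcc_domain_error")
  args <- vctrs_recycle(n = n, p = p, m = m)
  purrr::pmap_dbl(args, function(n, p, m) {
    k <- seq_len(n)
    sum(choose(n, k) * (1 - m)^k * m^(n - k) * (1 - (1 - p)^k)) / (1 - m^n)
  })
}

# minimal common-length recycling for scalar-or-vector arguments
vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(vapply(args, length, 1L))
  lapply(args, rep_len, length.out = len)
}

#' Expected colocalization ratio for candidate oligomeric states
#'
#' @param n Oligomeric states.
#' @param p Recall rate.
#' @param m Double-loss probability, or `NULL` for the simple model.
#' @return Expected background-corrected colocalization ratios.
#' @export
dcc_expected <- function(n, p, m = NULL) {
  if (is.null(m) || identical(m, 0)) pd_simple(n, p) else pd_modified(n, p, m)
}

# grid of candidate parameters, ordered lexicographically by (m, p) so that
# which.min resolves ties toward the smallest pair
dcc_grid <- function(model, p_max = 0.4, m_max = 1, step = 0.01) {
  p_seq <- seq(0, p_max, by = step)
  if (model == "simple") {
    tibble::tibble(m = 0, p = p_seq)
  } else {
    m_seq <- seq(0, m_max, by = step)
    m_seq <- m_seq[m_seq < 1] # m = 1 is degenerate
    tidyr::expand_grid(m = m_seq, p = p_seq)
  }
}

# G x length(n_values) matrix of expected ratios over the grid
dcc_grid_expected <- function(grid, n_values) {
  E <- matrix(0, nrow(grid), length(n_values))
  for (j in seq_along(n_values)) {
    n <- n_values[j]
    k <- seq_len(n)
    acc <- 0
    for (kk in k) {
      acc <- acc + choose(n, kk) * (1 - grid$m)^kk * grid$m^(n - kk) *
        (1 - (1 - grid$p)^kk)
    }
    E[, j] <- acc / (1 - grid$m^n)
  }
  E
}

#' Fit the DCC detection model to calibration data by grid search
#'
#' Scans the parameter grid (`p` from 0 to `p_max`, and for the double-loss
#' model `m` from 0 to 1, both in steps of `step`) and returns the grid point
#' maximizing the coefficient of determination R^2 between observed
#' colocalization ratios of reference proteins with known oligomeric state
#' and the model's expected ratios. Ties resolve to the smallest `(m, p)`.
#'
#' @param data A data frame with columns `n` (known oligomeric state) and
#'   `pd` (colocalization ratio), one row per cell; an optional `protein`
#'   column identifies the reference proteins.
#' @param model `"modified"` (double-loss, default) or `"simple"`.
#' @param use `"cells"` fits every per-cell observation; `"means"` collapses
#'   to per-protein mean ratios first (one observation per reference).
#' @param p_max,step Grid extent and increment.
#' @param n_max Largest candidate oligomeric state for which expected ratios
#'   are reported.
#'
#' @return An object of class `"dcc_fit"`: fitted `p` (and `m`), `r_squared`,
#'   expected ratios per state and the fitting setup. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' cal <- tibble::tibble(
#'   protein = c("mono", "di_a", "di_b", "tri", "tetra"),
#'   n = c(1, 2, 2, 3, 4),
#'   pd = c(0.172, 0.237, 0.241, 0.293, 0.411))
#' fit_dcc(cal, model = "simple", use = "means")
#' @export
fit_dcc <- function(data, model = c("modified", "simple"),
                    use = c("cells", "means"), p_max = 0.4, step = 0.01,
                    n_max = 4) {
  model <- match.arg(model)
  use <- match.arg(use)
  if (!nrow(data)) abort("empty calibration data.", class = "dcc_fit_error")
  if (model == "modified" && length(unique(data$n)) < 2)
    abort("the double-loss model needs at least two distinct oligomeric states.",
          class = "dcc_fit_error")
  obs <- if (use == "means") {
    grp <- if ("protein" %in% names(data)) c("protein", "n") else "n"
    data |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(pd = mean(.data$pd), .groups = "drop")
  } else data

  grid <- dcc_grid(model, p_max = p_max, step = step)
  n_values <- sort(unique(obs$n))
  E <- dcc_grid_expected(grid, n_values)
  # sufficient statistics per state: SSE(g) = sum_n N_n E^2 - 2 E S_n + SS_n
  stats_n <- obs |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(N = dplyr::n(), S = sum(.data$pd),
                     SS = sum(.data$pd^2), .groups = "drop") |>
    dplyr::arrange(.data$n)
  sse <- as.vector(E^2 %*% stats_n$N - 2 * E %*% stats_n$S) + sum(stats_n$SS)
  best <- which.min(sse)
  sstot <- sum((obs$pd - mean(obs$pd))^2)
  fit <- structure(list(
    model = model, use = use,
    p = grid$p[best],
    m = if (model == "modified") grid$m[best] else NULL,
    r_squared = 1 - sse[best] / sstot,
    expected = tibble::tibble(
      n = seq_len(n_max),
      e = dcc_expected(seq_len(n_max), grid$p[best],
                       if (model == "modified") grid$m[best] else NULL)),
    grid = list(p_max = p_max, step = step),
    n_obs = nrow(obs), data = data, n_max = n_max),
    class = "dcc_fit")
  fit
}

#' @export
print.dcc_fit <- function(x, ...) {
  cat("DCC detection model fit (", x$model, " model, per-",
      if (x$use == "cells") "cell observations" else "protein means",
      ")\n", sep = "")
  if (!is.null(x$m)) cat(sprintf("  m = %.2f (double-loss)\n", x$m))
  cat(sprintf("  p = %.2f (indicator recall rate)\n", x$p))
  cat(sprintf("  R^2 = %.3f over %d observations\n", x$r_squared, x$n_obs))
  cat("  expected ratios:",
      paste(sprintf("E(%d)=%.3f", x$expected$n, x$expected$e), collapse = ", "),
      "\n")
  invisible(x)
}

#' Coefficient of mismatch between observed ratios and a candidate state
#'
#' Compares per-cell colocalization ratios to the expected ratio `E(n)` of a
#' candidate oligomeric state:
#'
#'   M^2(n) = 1 - sum_i (x_i - xbar)^2 / sum_i (x_i - E(n))^2
#'
#' Zero indicates a perfect match (`E(n)` equals the sample mean); values
#' approach one as `E(n)` moves far from the data.
#'
#' @param x Per-cell colocalization ratios (at least two).
#' @param e_n Expected ratio for the candidate state.
#' @return The mismatch coefficient.
#' @export
mismatch <- function(x, e_n) {
  if (length(x) < 2)
    abort("need at least two observations.", class = "dcc_domain_error")
  num <- sum((x - mean(x))^2)
  den <- sum((x - e_n)^2)
  if (den == 0) return(0)
  1 - num / den
}

#' Two-sample Kolmogorov-Smirnov comparison with Bonferroni threshold
#'
#' Compares the per-cell colocalization ratios of a protein of interest with
#' those of a reference protein of known oligomeric state. The rejection
#' threshold is Bonferroni-corrected for the number of candidate states
#' compared (default 4: alpha' = 0.05 / 4 = 0.0125). The exact p-value is
#' used for small samples (both sizes at most 25), the asymptotic one
#' otherwise.
#'
#' @param poi,ref Numeric vectors of per-cell ratios.
#' @param alpha Family-wise error level.
#' @param n_comparisons Number of comparisons for the Bonferroni correction.
#' @return A one-row tibble: `statistic` (D), `p_value`, `alpha_adj`,
#'   `reject` (distributions differ at the corrected level).
#' @export
ks_compare <- function(poi, ref, alpha = 0.05, n_comparisons = 4) {
  if (!length(poi) || !length(ref))
    abort("both samples must be nonempty.", class = "dcc_domain_error")
  exact <- min(length(poi), length(ref)) <= 25
  kt <- suppressWarnings(ks.test(poi, ref, exact = exact))
  alpha_adj <- alpha / n_comparisons
  tibble::tibble(statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 alpha_adj = alpha_adj,
                 reject = kt$p.value < alpha_adj)
}

#' Separation of adjacent oligomeric states across the parameter space
#'
#' For each `(m, p)` pair, computes the minimum gap between the expected
#' colocalization ratios of consecutive oligomeric states up to `n_max`.
#' Larger gaps mean adjacent states are easier to distinguish; the gap
#' shrinks at large `p` (saturation) and at large `m`.
#'
#' @param n_max Largest state considered.
#' @param p_grid,m_grid Parameter grids.
#' @return A tibble with `m`, `p` and `separation` (the minimal adjacent-state
#'   gap in expected ratio).
#' @export
sensitivity_surface <- function(n_max = 5,
                                p_grid = seq(0, 1, 0.02),
                                m_grid = seq(0, 0.95, 0.05)) {
  grid <- tidyr::expand_grid(m = m_grid, p = p_grid)
  E <- dcc_grid_expected(grid, seq_len(n_max))
  grid$separation <- apply(E, 1, function(e) min(diff(e)))
  grid
}

#' Classify the oligomeric state by bootstrap mismatch and K-S tests
#'
#' Infers the oligomeric state of a protein of interest (POI) from its
#' per-cell colocalization ratios, given calibration data from reference
#' proteins with known states. For each bootstrap resample the reference
#' cells of every protein and the POI cells are resampled with replacement,
#' the detection model is refitted on the resampled calibration, and the
#' mismatch coefficient M^2(n) is recomputed for every candidate state, so
#' the reported confidence intervals carry the combined uncertainty of the
#' calibration and the POI measurement. The inferred state `n_star` minimizes
#' the mean bootstrap M^2. Two-sample Kolmogorov-Smirnov tests against each
#' reference protein (Bonferroni-corrected) provide a model-free cross-check.
#'
#' @param poi Numeric vector of POI per-cell ratios, or a data frame with a
#'   `pd` column.
#' @param cal Calibration data as for [fit_dcc()] (columns `protein`, `n`,
#'   `pd`, one row per cell).
#' @param model,use,p_max,step Passed to [fit_dcc()].
#' @param n_max Largest candidate state.
#' @param B Number of bootstrap resamples (at least 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param alpha Family-wise error level for the K-S tests.
#' @param conf_level Bootstrap (percentile) confidence level.
#'
#' @return An object of class `"dcc_classification"`: per-state table with
#'   full-data M^2, bootstrap mean and CI; `n_star`; K-S comparisons; the
#'   full-data fit; bootstrap parameter summaries. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
classify_dcc <- function(poi, cal, model = c("modified", "simple"),
                         use = "cells", n_max = 4, B = 10000, seed = NULL,
                         alpha = 0.05, p_max = 0.4, step = 0.01,
                         conf_level = 0.95) {
  model <- match.arg(model)
  if (is.data.frame(poi)) poi <- poi$pd
  if (B < 1000) abort("B must be at least 1000.", class = "dcc_domain_error")
  if (!is.null(seed)) set.seed(seed)

  fit <- fit_dcc(cal, model = model, use = use, p_max = p_max, step = step,
                 n_max = n_max)
  m2_full <- vapply(seq_len(n_max),
                    function(n) mismatch(poi, fit$expected$e[n]), 1)

  grid <- dcc_grid(model, p_max = p_max, step = step)
  E_cand <- dcc_grid_expected(grid, seq_len(n_max)) # G x n_max
  # per-protein observation lists for resampling
  cal$protein <- if ("protein" %in% names(cal)) cal$protein else paste0("ref_n", cal$n)
  by_prot <- split(cal$pd, cal$protein)
  prot_n <- vapply(split(cal$n, cal$protein), function(v) v[1], 1)
  n_values <- sort(unique(prot_n))
  E_cal <- dcc_grid_expected(grid, n_values) # G x |n_values|
  n_poi <- length(poi)

  m2_boot <- matrix(NA_real_, B, n_max)
  par_boot <- matrix(NA_real_, B, 2, dimnames = list(NULL, c("m", "p")))
  chunk <- 1000L
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    # resampled sufficient statistics per protein -> per state
    S <- matrix(0, length(n_values), b)
    SS_tot <- numeric(b)
    N_state <- numeric(length(n_values))
    for (pr in names(by_prot)) {
      xs <- by_prot[[pr]]
      if (use == "means") {
        # resample cells, use the resampled per-protein mean as one observation
        draw <- matrix(xs[sample.int(length(xs), length(xs) * b, replace = TRUE)],
                       length(xs), b)
        mu <- colMeans(draw)
        j <- match(prot_n[[pr]], n_values)
        S[j, ] <- S[j, ] + mu
        SS_tot <- SS_tot + mu^2
        if (done == 0) N_state[j] <- N_state[j] + 1
      } else {
        draw <- matrix(xs[sample.int(length(xs), length(xs) * b, replace = TRUE)],
                       length(xs), b)
        j <- match(prot_n[[pr]], n_values)
        S[j, ] <- S[j, ] + colSums(draw)
        SS_tot <- SS_tot + colSums(draw^2)
        if (done == 0) N_state[j] <- N_state[j] + length(xs)
      }
    }
    if (done > 0) {
      # N_state is resample-invariant; recompute once
      N_state <- N_state_saved
    }
    N_state_saved <- N_state
    sse <- matrix(E_cal^2 %*% N_state, nrow(grid), b) - 2 * (E_cal %*% S) +
      matrix(SS_tot, nrow(grid), b, byrow = TRUE)
    best <- max.col(-t(sse), ties.method = "first")
    par_boot[done + seq_len(b), "m"] <- grid$m[best]
    par_boot[done + seq_len(b), "p"] <- grid$p[best]
    # resample POI and evaluate M^2 against refitted expected ratios
    draw_poi <- matrix(poi[sample.int(n_poi, n_poi * b, replace = TRUE)],
                       n_poi, b)
    mu_poi <- colMeans(draw_poi)
    css_poi <- colSums(draw_poi^2) - n_poi * mu_poi^2
    for (n in seq_len(n_max)) {
      e_b <- E_cand[best, n]
      den <- css_poi + n_poi * (mu_poi - e_b)^2
      m2 <- ifelse(den == 0, 0, 1 - css_poi / den)
      m2_boot[done + seq_len(b), n] <- m2
    }
    done <- done + b
  }

  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  tab <- tibble::tibble(
    n = seq_len(n_max),
    expected = fit$expected$e,
    m2 = m2_full,
    m2_mean = colMeans(m2_boot),
    m2_lo = apply(m2_boot, 2, quantile, qs[1]),
    m2_hi = apply(m2_boot, 2, quantile, qs[2]))
  n_star <- tab$n[which.min(tab$m2_mean)]

  ks <- purrr::imap_dfr(by_prot, function(xs, pr) {
    dplyr::bind_cols(tibble::tibble(reference = pr, ref_n = prot_n[[pr]]),
                     ks_compare(poi, xs, alpha = alpha,
                                n_comparisons = n_max))
  }) |> dplyr::arrange(.data$ref_n)

  structure(list(states = tab, n_star = n_star, ks = ks, fit = fit,
                 boot_params = tibble::tibble(
                   parameter = c("m", "p"),
                   mean = c(mean(par_boot[, "m"]), mean(par_boot[, "p"])),
                   lo = c(quantile(par_boot[, "m"], qs[1]),
                          quantile(par_boot[, "p"], qs[1])),
                   hi = c(quantile(par_boot[, "m"], qs[2]),
                          quantile(par_boot[, "p"], qs[2]))),
                 B = B, n_poi = n_poi, alpha = alpha,
                 conf_level = conf_level),
            class = "dcc_classification")
}

#' @export
print.dcc_classification <- function(x, ...) {
  cat("DCC oligomeric-state classification (", x$B, " bootstrap resamples)\n",
      sep = "")
  cat(sprintf("  inferred state n* = %d\n", x$n_star))
  df <- as.data.frame(x$states)
  df[-1] <- lapply(df[-1], round, 3)
  print(df, row.names = FALSE)
  cat("K-S tests vs references (alpha' = ",
      format(x$ks$alpha_adj[1]), "):\n", sep = "")
  ks <- as.data.frame(x$ks[, c("reference", "ref_n", "statistic", "p_value", "reject")])
  ks$statistic <- round(ks$statistic, 3)
  ks$p_value <- signif(ks$p_value, 3)
  print(ks, row.names = FALSE)
  invisible(x)
}
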