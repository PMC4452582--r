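#' Saltelli cross-sample for Sobol' index estimation
#'
#' Generates the radial Saltelli design used to estimate first- and
#' total-order Sobol' indices: two independent uniform base matrices A and B
#' of `n_base` rows, plus the k cross matrices AB_i (A with column i taken
#' from B), stacked as `n_base * (k + 2)` rows in the order
#' `A, B, AB_1, ..., AB_k`.
#'
#' Rows violating the structural constraints of the community model
#' (`K_rc > x_c`, `K_rr > x_r`, needed so the grazer numerical-response
#' denominators cannot vanish) are rejected and redrawn; the constraint is
#' enforced jointly across the A/B pair so every cross row is valid too.
#'
#' @param ranges a named list of `c(low, high)` ranges, one per parameter.
#' @param n_base base sample size n (>= 64 for usable estimates).
#' @param seed integer seed; the design is deterministic given the seed.
#' @return A numeric matrix with `n_base * (k + 2)` rows and named columns,
#'   with attributes `n_base` and `k`.
#' @examples
#' saltelli_sample(list(a = c(0, 1), b = c(0, 1)), n_base = 64, seed = 1)
#' @export
saltelli_sample <- function(ranges, n_base, seed = 20090101L) {
  stopifnot(is.list(ranges), length(ranges) >= 1, !is.null(names(ranges)))
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(lo >= hi)) {
    stop("degenerate range (low >= high) for: ",
         paste(names(ranges)[lo >= hi], collapse = ", "))
  }
  if (n_base < 64) stop("n_base must be >= 64")
  k <- length(ranges)
  nm <- names(ranges)
  set.seed(as.integer(seed))
  draw <- function(n) {
    matrix(runif(n * k), nrow = n, ncol = k, dimnames = list(NULL, nm)) %*%
      diag(hi - lo, k) + matrix(lo, n, k, byrow = TRUE)
  }
  A <- draw(n_base)
  B <- draw(n_base)
  colnames(A) <- colnames(B) <- nm
  ok <- function(A, B) {
    valid <- rep(TRUE, nrow(A))
    for (pair in list(c("K_rc", "x_c"), c("K_rr", "x_r"))) {
      if (all(pair %in% nm)) {
        # every A/B column mix of the pair must satisfy K > x
        valid <- valid &
          pmin(A[, pair[1]], B[, pair[1]]) > pmax(A[, pair[2]], B[, pair[2]])
      }
    }
    valid
  }
  bad <- which(!ok(A, B))
  while (length(bad)) {
    A[bad, ] <- draw(length(bad))
    B[bad, ] <- draw(length(bad))
    bad <- which(!ok(A, B))
  }
  blocks <- vector("list", k + 2)
  blocks[[1]] <- A
  blocks[[2]] <- B
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    blocks[[i + 2]] <- ABi
  }
  out <- do.call(rbind, blocks)
  attr(out, "n_base") <- n_base
  attr(out, "k") <- k
  out
}

#' Sobol' first- and total-order indices from Saltelli model outputs
#'
#' Estimates first-order (S1) and total-order (ST) variance-based
#' sensitivity indices from model outputs evaluated row-by-row on a
#' [saltelli_sample()] design, using the standard estimators
#' \deqn{S1_i = \frac{\mathrm{mean}(y_B (y_{AB_i} - y_A))}{V},\qquad
#'       ST_i = \frac{\mathrm{mean}((y_A - y_{AB_i})^2)}{2V},}
#' with V the variance over the combined A and B outputs. Confidence
#' half-widths come from a seeded bootstrap over base-sample rows
#' (2.5%-97.5% quantile half-range).
#'
#' Raw estimates are retained in columns `S1` and `ST`; `S1_clipped` and
#' `ST_clipped` additionally restrict them to \[0, 1\] for reporting.
#'
#' @param y numeric vector of model outputs, length `n_base * (k + 2)`,
#'   ordered as the rows of the sample matrix.
#' @param sample the matrix returned by [saltelli_sample()] (used for its
#'   dimensions and parameter names); alternatively supply `n_base` and
#'   `parameters`.
#' @param n_base,parameters base sample size and parameter names, when
#'   `sample` is not given.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed seed for the bootstrap resampling.
#' @return A tibble of class `sobol_result`: `parameter`, `S1`, `ST`,
#'   `S1_ci`, `ST_ci`, `S1_clipped`, `ST_clipped`, with attributes `n_base`
#'   and `variance`.
#' @export
sobol_indices <- function(y, sample = NULL, n_base = attr(sample, "n_base"),
                          parameters = colnames(sample), n_boot = 200,
                          seed = 20090101L) {
  k <- length(parameters)
  stopifnot(k >= 1, length(y) == n_base * (k + 2))
  if (any(!is.finite(y))) stop("model outputs must be finite")
  y <- y - mean(y[seq_len(2 * n_base)])  # centering cuts estimator variance
  yA <- y[seq_len(n_base)]
  yB <- y[n_base + seq_len(n_base)]
  yAB <- matrix(y[-(1:(2 * n_base))], nrow = n_base, ncol = k)
  est <- function(idx) {
    a <- yA[idx]; b <- yB[idx]; ab <- yAB[idx, , drop = FALSE]
    v <- var(c(a, b))
    if (v == 0) return(NULL)
    S1 <- colMeans(b * (ab - a)) / v
    ST <- colMeans((a - ab)^2) / (2 * v)
    list(S1 = S1, ST = ST, v = v)
  }
  full <- est(seq_len(n_base))
  if (is.null(full)) stop("zero output variance; all indices undefined")
  set.seed(as.integer(seed))
  boots <- replicate(n_boot, {
    e <- est(sample.int(n_base, replace = TRUE))
    if (is.null(e)) c(rep(NA_real_, 2 * k)) else c(e$S1, e$ST)
  })
  half <- apply(boots, 1, function(x) {
    q <- quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    (q[2] - q[1]) / 2
  })
  out <- tibble::tibble(
    parameter = parameters,
    S1 = full$S1, ST = full$ST,
    S1_ci = half[seq_len(k)], ST_ci = half[k + seq_len(k)],
    S1_clipped = pmin(pmax(full$S1, 0), 1),
    ST_clipped = pmin(pmax(full$ST, 0), 1)
  )
  attr(out, "n_base") <- n_base
  attr(out, "variance") <- full$v
  class(out) <- c("sobol_result", class(out))
  out
}

#' Rank parameters by first-order sensitivity
#'
#' @param result a `sobol_result` tibble.
#' @param k how many parameters to return; if larger than the parameter
#'   count the full ranking is returned.
#' @return The top-k rows sorted by `S1` descending, ties broken by `ST`
#'   then by parameter name.
#' @export
rank_top_k <- function(result, k = 5) {
  stopifnot(all(c("parameter", "S1", "ST") %in% names(result)))
  ord <- order(-result$S1, -result$ST, result$parameter)
  res <- result[ord, ]
  res[seq_len(min(k, nrow(res))), ]
}

#' Default sensitivity ranges: uniform +/-50% around nominal values
#'
#' The published study reports no sampling ranges; the package default
#' explores each of the 23 rate/affinity/quota/threshold parameters
#' uniformly within half and one-and-a-half times its nominal value
#' (temperature is not varied).
#'
#' @param params a [plankton_params()] object supplying nominal values.
#' @param spread half-width as a fraction of the nominal value (default 0.5).
#' @return Named list of `c(low, high)` ranges.
#' @export
sensitivity_ranges <- function(params = plankton_params(), spread = 0.5) {
  vary <- setdiff(names(params), "Temp")
  setNames(lapply(vary, function(nm) {
    v <- params[[nm]]
    c((1 - spread) * v, (1 + spread) * v)
  }), vary)
}

#' Global sensitivity analysis of 30-day community simulations
#'
#' Runs the full-community model (all members active, Table-1-style initial
#' abundances) once per row of a Saltelli design and estimates Sobol'
#' first- and total-order indices of a scalar trajectory summary for the
#' uninfected-host (H), infected-host (I) and dinospore (P) pools. The
#' default summary is the time-averaged abundance over the run, which is
#' robust to peak-timing shifts; maxima and final values are also available.
#'
#' @param trophic `"oligo"` (1 uM) or `"eutro"` (36 uM nitrate).
#' @param n_base Saltelli base sample size; total model runs are
#'   `n_base * 25` for the 23 varied parameters.
#' @param seed integer seed controlling sampling and bootstrap.
#' @param ranges parameter ranges, as from [sensitivity_ranges()].
#' @param output_stat `"mean"`, `"max"` or `"final"` trajectory summary.
#' @param outputs which state variables to analyse.
#' @param rtol integration tolerance for the batch runs.
#' @param output_step trajectory output step for the batch runs (days).
#' @param options a [model_options()] object.
#' @param .progress print a dot every 100 runs.
#' @return A tibble: one `sobol_result` per output variable, bound by rows
#'   with an `output` column; attributes `trophic`, `seed`, `n_base`,
#'   `output_stat`.
#' @export
sobol_community <- function(trophic = c("eutro", "oligo"), n_base = 128,
                            seed = 20090101L,
                            ranges = sensitivity_ranges(),
                            output_stat = c("mean", "max", "final"),
                            outputs = c("H", "I", "P"),
                            rtol = 1e-8, output_step = 0.1,
                            options = model_options(), .progress = FALSE) {
  trophic <- match.arg(trophic)
  output_stat <- match.arg(output_stat)
  X <- saltelli_sample(ranges, n_base, seed)
  init <- table1_defaults()$initial
  init[["N"]] <- .nitrate_for(trophic)
  mask <- community_mask()
  stat_fun <- switch(output_stat, mean = mean, max = max,
                     final = function(x) x[length(x)])
  Y <- matrix(NA_real_, nrow(X), length(outputs),
              dimnames = list(NULL, outputs))
  for (i in seq_len(nrow(X))) {
    p <- do.call(plankton_params, as.list(X[i, ]))
    sim <- simulate_community(initial = init, mask = mask, horizon = 30,
                              params = p, output_step = output_step,
                              rtol = rtol, options = options)
    Y[i, ] <- vapply(outputs, function(v) stat_fun(sim$trajectory[[v]]),
                     numeric(1))
    if (.progress && i %% 100 == 0) cat(".")
  }
  if (.progress) cat("\n")
  res <- purrr::map_dfr(outputs, function(v) {
    r <- sobol_indices(Y[, v], X, n_boot = 200, seed = seed)
    r$output <- v
    r
  })
  res <- res[, c("output", setdiff(names(res), "output"))]
  class(res) <- c("sobol_result", class(tibble::tibble()))
  attr(res, "trophic") <- trophic
  attr(res, "seed") <- seed
  attr(res, "n_base") <- n_base
  attr(res, "output_stat") <- output_stat
  res
}

#' @rdname sobol_indices
#' @param x a `sobol_result` object.
#' @param ... unused.
#' @method tidy sobol_result
#' @export
tidy.sobol_result <- function(x, ...) {
  cols <- intersect(c("output", "parameter", "S1", "ST", "S1_ci", "ST_ci"),
                    names(x))
  out <- tibble::as_tibble(unclass(x)[cols])
  dplyr::arrange(out, dplyr::across(dplyr::any_of("output")), dplyr::desc(.data$S1))
}

#' @rdname sobol_indices
#' @method glance sobol_result
#' @export
glance.sobol_result <- function(x, ...) {
  tibble::tibble(
    n_base = attr(x, "n_base"),
    n_parameters = length(unique(x$parameter)),
    trophic = attr(x, "trophic") %||% NA_character_,
    output_stat = attr(x, "output_stat") %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
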