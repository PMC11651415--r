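#' Extended FAST variance-based sensitivity analysis
#'
#' Classic extended Fourier amplitude sensitivity test: each parameter in
#' turn is assigned the highest search-curve frequency while the remaining
#' parameters oscillate at low complementary frequencies; first-order
#' indices (S1) come from the spectral power at the driving frequency and
#' its harmonics, total indices (ST) from the complement of the power at
#' the low frequencies.  Includes the simplex-constraint transform used for
#' the FLTB/FSTB/FOTB dry-matter partition triplets.
#'
#' @name sensitivity_efast
NULL

#' Parameter specification for the sensitivity design
#'
#' @param name Character vector of parameter symbols.
#' @param lower,upper Numeric bounds (lower < upper).
#' @return Data frame of class \code{param_spec}.
#' @export
param_spec <- function(name, lower, upper) {
  stopifnot(length(name) == length(lower), length(lower) == length(upper))
  if (any(lower >= upper))
    stop("each parameter needs lower < upper", call. = FALSE)
  structure(data.frame(name = name, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("param_spec", "data.frame"))
}

#' Generate an extended FAST design
#'
#' Samples-per-parameter \code{n} must satisfy the design rule n >= 65 p.
#' The design has \code{n * p} rows grouped in p blocks; in block i,
#' parameter i carries the maximum frequency and the others complementary
#' low frequencies.  Values follow the search curve
#' x(s) = 0.5 + asin(sin(w s + phi)) / pi mapped to [lower, upper], with
#' seeded random phase shifts.
#'
#' @param specs A \code{param_spec} (or data frame with name/lower/upper).
#' @param n Samples per parameter.
#' @param seed Integer seed for the phase shifts.
#' @param M Number of harmonics (interference factor), default 4.
#' @return An \code{efast_design}: list with the run matrix
#'   (\code{samples}, n*p rows), \code{n}, \code{p}, \code{M},
#'   \code{omega_max}, \code{specs}, \code{seed}.
#' @export
generate_design <- function(specs, n, seed = 1L, M = 4L) {
  p <- nrow(specs)
  stopifnot(p >= 1)
  need <- 65L * p
  if (n < need)
    stop("extended FAST requires the sample count to exceed 65 times the ",
         "number of parameters: n = ", n, " < required minimum ", need,
         " for p = ", p, call. = FALSE)
  omega_max <- floor((n - 1) / (2 * M))
  if (omega_max < 2)
    stop("n too small for M = ", M, " harmonics", call. = FALSE)
  other_max <- max(1L, floor(omega_max / (2 * M)))
  s <- 2 * pi * (seq_len(n) - 1) / n
  rng <- local_rng(seed)
  X <- matrix(NA_real_, n * p, p,
              dimnames = list(NULL, specs$name))
  for (i in seq_len(p)) {
    omega <- rep_len(seq_len(other_max), p)
    omega[i] <- omega_max
    phi <- rng$unif(p) * 2 * pi
    rows <- (i - 1L) * n + seq_len(n)
    for (j in seq_len(p)) {
      g <- 0.5 + asin(sin(omega[j] * s + phi[j])) / pi
      X[rows, j] <- specs$lower[j] + g * (specs$upper[j] - specs$lower[j])
    }
  }
  structure(list(samples = X, n = as.integer(n), p = p, M = as.integer(M),
                 omega_max = omega_max, specs = specs, seed = seed),
            class = "efast_design")
}

#' @export
print.efast_design <- function(x, ...) {
  cat("Extended FAST design: p = ", x$p, ", n = ", x$n, " per parameter (",
      nrow(x$samples), " runs), omega_max = ", x$omega_max, ", M = ", x$M,
      "\n", sep = "")
  invisible(x)
}

#' Apply the simplex constraint to partition-coefficient triplets
#'
#' For every development stage with an FLTB/FSTB/FOTB triplet in the design,
#' each row is transformed sequentially: the leaf fraction is rescaled to
#' [0, 1], the stem fraction to [0, 1 - FL], and the storage-organ fraction
#' set to the remainder, so FL + FS + FO = 1 with all three non-negative.
#' Columns outside the triplets are untouched.
#'
#' @param design An \code{efast_design}.
#' @param triplets Optional list of character triplets
#'   \code{c(FL, FS, FO)} column names; auto-detected from the
#'   \code{FLTB<dvs>}/\code{FSTB<dvs>}/\code{FOTB<dvs>} naming when NULL.
#' @return The design with the triplet columns replaced.
#' @export
apply_partition_constraint <- function(design, triplets = NULL) {
  stopifnot(inherits(design, "efast_design"))
  cn <- colnames(design$samples)
  if (is.null(triplets)) {
    tags <- unique(sub("^FLTB", "", grep("^FLTB", cn, value = TRUE)))
    triplets <- lapply(tags, function(d)
      paste0(c("FLTB", "FSTB", "FOTB"), d))
  }
  for (tri in triplets) {
    miss <- setdiff(tri, cn)
    if (length(miss))
      stop("partition triplet member(s) missing from design: ",
           paste(miss, collapse = ", "), call. = FALSE)
    sp <- design$specs
    b <- function(nm) {
      k <- match(nm, sp$name)
      c(sp$lower[k], sp$upper[k])
    }
    unit <- function(v, bb) (v - bb[1]) / (bb[2] - bb[1])
    fl <- unit(design$samples[, tri[1]], b(tri[1]))
    fs_u <- unit(design$samples[, tri[2]], b(tri[2]))
    fs <- fs_u * (1 - fl)
    fo <- 1 - fl - fs
    design$samples[, tri[1]] <- fl
    design$samples[, tri[2]] <- fs
    design$samples[, tri[3]] <- fo
    design$constrained <- union(design$constrained, tri)
  }
  design
}

#' Compute first-order and total sensitivity indices
#'
#' Spectral extended-FAST estimator: per parameter block, S1 is the power
#' at the driving frequency and its M harmonics over the total variance;
#' ST is one minus the share of power at the complementary low frequencies.
#' Parameters whose columns were overwritten by the simplex-constraint
#' transform are flagged \code{approximate} in the result, since the
#' overwrite distorts their pure search-curve structure.
#'
#' @param design An \code{efast_design}.
#' @param outputs Numeric vector, one model output per design row, or a
#'   matrix/data frame with one column per output label.
#' @return An \code{efast_result}: data frame (parameter, output, S1, ST,
#'   approximate).
#' @export
compute_indices <- function(design, outputs) {
  stopifnot(inherits(design, "efast_design"))
  Y <- as.matrix(outputs)
  if (nrow(Y) != nrow(design$samples))
    stop("outputs length must equal the number of design rows (",
         nrow(design$samples), ")", call. = FALSE)
  if (any(!is.finite(Y)))
    stop("outputs must be finite", call. = FALSE)
  if (is.null(colnames(Y)))
    colnames(Y) <- if (ncol(Y) == 1) "output" else
      paste0("output", seq_len(ncol(Y)))
  n <- design$n; p <- design$p; M <- design$M; wmax <- design$omega_max
  res <- do.call(rbind, lapply(colnames(Y), function(lab) {
    y_all <- Y[, lab]
    s1 <- st <- numeric(p)
    for (i in seq_len(p)) {
      y <- y_all[(i - 1L) * n + seq_len(n)]
      if (stats::var(y) == 0)
        stop("output '", lab, "' has zero variance over block ", i,
             "; indices undefined", call. = FALSE)
      spec <- Mod(stats::fft(y) / n)^2
      half <- floor((n - 1) / 2)
      pw <- spec[2:(half + 1)]           # frequencies 1..half
      V <- 2 * sum(pw)
      D1 <- 2 * sum(pw[(1:M) * wmax])
      Dt <- 2 * sum(pw[seq_len(floor(wmax / 2))])
      s1[i] <- D1 / V
      st[i] <- 1 - Dt / V
    }
    data.frame(parameter = design$specs$name, output = lab,
               S1 = s1, ST = st,
               approximate = design$specs$name %in% design$constrained,
               stringsAsFactors = FALSE)
  }))
  structure(res, class = c("efast_result", "data.frame"))
}

#' @export
print.efast_result <- function(x, ...) {
  cat("Extended FAST sensitivity indices\n")
  df <- as.data.frame(x)
  df <- df[order(df$output, -df$ST), ]
  print(utils::head(df, 20), digits = 3, row.names = FALSE)
  if (nrow(df) > 20) cat("  ... ", nrow(df) - 20, " more rows\n")
  invisible(x)
}

#' Rank parameters by total sensitivity
#'
#' @param result An \code{efast_result}.
#' @param k Number of parameters to return (default: all).
#' @param output Output label to rank on (default: first).
#' @return Character vector of parameter symbols, strongest first (ties
#'   broken by S1, then name).
#' @export
rank_parameters <- function(result, k = NULL, output = NULL) {
  df <- as.data.frame(result)
  if (is.null(output)) output <- df$output[1]
  df <- df[df$output == output, ]
  if (is.null(k)) k <- nrow(df)
  if (k > nrow(df))
    stop("k = ", k, " exceeds the number of parameters (", nrow(df), ")",
         call. = FALSE)
  ord <- order(-df$ST, -df$S1, df$parameter)
  df$parameter[ord][seq_len(k)]
}

#' Run a sensitivity analysis of the growth engine
#'
#' Convenience wrapper: builds the design over the requested symbols
#' (bounds from [param_bounds()] or a relative half-width around the
#' current value), applies the partition constraint to any FLTB/FSTB/FOTB
#' triplets present, runs the engine for every row and computes indices for
#' the requested outputs.
#'
#' @param params Baseline \code{crop_params}.
#' @param weather A \code{weather_series}.
#' @param symbols Parameter symbols to vary.
#' @param n Samples per parameter.
#' @param outputs Any of \code{"LAIMAX"}, \code{"TWSO"}, \code{"TAGP"}.
#' @param rel_width If non-NULL, bounds are value * (1 +/- rel_width)
#'   (e.g. 0.1 for the +/-10 percent convention) instead of the registry
#'   bounds.
#' @param seed Integer seed.
#' @param mode,interception Engine settings.
#' @return An \code{efast_result}.
#' @export
efast_engine <- function(params, weather, symbols, n,
                         outputs = c("LAIMAX", "TWSO", "TAGP"),
                         rel_width = NULL, seed = 1L,
                         mode = "potential", interception = "tpai") {
  outputs <- match.arg(outputs, several.ok = TRUE)
  if (!is.null(rel_width)) {
    v <- vapply(symbols, function(s) get_param(params, s), 0)
    lo <- v * (1 - rel_width); hi <- v * (1 + rel_width)
    flat <- hi - lo <= 0
    lo[flat] <- v[flat] - rel_width; hi[flat] <- v[flat] + rel_width
    specs <- param_spec(symbols, lo, hi)
  } else {
    b <- param_bounds(symbols)
    specs <- param_spec(b$symbol, b$lower, b$upper)
  }
  design <- apply_partition_constraint(generate_design(specs, n, seed))
  weather <- ensure_radiation(weather)
  Y <- matrix(NA_real_, nrow(design$samples), length(outputs),
              dimnames = list(NULL, outputs))
  for (r in seq_len(nrow(design$samples))) {
    pr <- params
    cn <- colnames(design$samples)
    for (j in seq_along(cn))
      pr <- set_param(pr, cn[j], design$samples[r, j],
                      renormalize = !cn[j] %in% design$constrained)
    tr <- run_simulation(pr, weather, mode = mode,
                         interception = interception)
    k <- nrow(tr)
    Y[r, ] <- c(LAIMAX = max(tr$LAI), TWSO = tr$TWSO[k],
                TAGP = tr$TAGP[k])[outputs]
  }
  compute_indices(design, Y)
}
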