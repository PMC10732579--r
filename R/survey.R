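#' Random isotopomer fraction vectors
#'
#' Samples ground-truth fraction vectors for the identifiability survey.
#' \code{"uniform_simplex"} draws from the symmetric Dirichlet(1), i.e.
#' uniformly on the simplex; \code{"beta_stick"} draws independent Beta(1,1)
#' variates and renormalizes (the sampler used for the aspartate survey).
#' An optional acetyl-CoA constraint rescales the labeling-pattern groups
#' after sampling, see \code{\link{acetylcoa_constrain}}.
#'
#' @param n number of vectors to draw.
#' @param molecule a \code{molecule_spec}, molecule name, or carbon count.
#' @param sampler \code{"uniform_simplex"} or \code{"beta_stick"}.
#' @param constraint \code{"none"} or \code{"acetylcoa"} (glutamate only).
#' @param limit acetyl-CoA constraint limit (minor species sum as a fraction
#'   of the major species).
#' @param major major acetyl-CoA group, see \code{\link{acetylcoa_constrain}}.
#' @return matrix with \code{n} rows, one fraction vector per row, columns in
#'   canonical labeling order.
#' @export
sample_fractions <- function(n, molecule = "glutamate",
                             sampler = c("uniform_simplex", "beta_stick"),
                             constraint = c("none", "acetylcoa"),
                             limit = 0.02, major = "11") {
  sampler <- match.arg(sampler)
  constraint <- match.arg(constraint)
  labs <- labeling_strings(molecule)
  k <- length(labs)
  X <- switch(sampler,
              uniform_simplex = matrix(stats::rexp(n * k), n, k),
              beta_stick = matrix(stats::runif(n * k), n, k))
  X <- X / rowSums(X)
  colnames(X) <- labs
  if (constraint == "acetylcoa") {
    for (r in seq_len(n)) X[r, ] <- acetylcoa_constrain(X[r, ], limit, major)
  }
  X
}

#' Constrain the acetyl-CoA composition of a glutamate fraction vector
#'
#' In a single-tracer experiment the acetyl-CoA pool feeding citrate synthase
#' is dominated by one labeled species. Glutamate C4-C5 report the acetyl-CoA
#' carbons (C4 = methyl, C5 = carbonyl), so the 32 isotopomers split into
#' pattern groups by their C4C5 bits: \code{"10"} ([2-13C]acetyl-CoA),
#' \code{"01"} ([1-13C]), \code{"11"} ([1,2-13C]) and \code{"00"} (unlabeled).
#' This function rescales the two minor labeled species so that together they
#' are at most \code{limit} times the major labeled species, then renormalizes.
#' The default major group \code{"11"} describes tracers producing
#' [1,2-13C]acetyl-CoA (uniformly labeled glucose, [1,2-13C]acetate);
#' \code{major = "auto"} picks the largest labeled group per sample.
#'
#' @param x glutamate fraction vector in canonical order.
#' @param limit allowed minor-to-major ratio, default 0.02.
#' @param major \code{"11"}, \code{"10"}, \code{"01"} or \code{"auto"}.
#' @return rescaled fraction vector summing to 1.
#' @export
acetylcoa_constrain <- function(x, limit = 0.02, major = "11") {
  stopifnot(length(x) == 32, limit > 0, limit < 1)
  labs <- labeling_strings(5L)
  c45 <- substr(labs, 4, 5)
  groups <- list("10" = c45 == "10", "01" = c45 == "01", "11" = c45 == "11")
  sums <- vapply(groups, function(g) sum(x[g]), numeric(1))
  mj <- if (identical(major, "auto")) names(which.max(sums)) else match.arg(major, names(groups))
  minor <- setdiff(names(groups), mj)
  msum <- sum(sums[minor])
  if (msum > limit * sums[mj]) {
    f <- limit * sums[mj] / msum
    for (g in minor) x[groups[[g]]] <- x[groups[[g]]] * f
  }
  x / sum(x)
}

#' Simulation survey of isotopomer recovery error
#'
#' Quantifies how well each isotopomer can be recovered from noiseless data:
#' for each trial a random ground-truth fraction vector is drawn, mapped
#' forward through the mapping matrix to per-family intensity fractions, and
#' deconvolved back; the signed recovery errors are aggregated per labeling
#' into the median, the 2.5th/97.5th percentiles and the maximum absolute
#' error. Isotopomers whose coordinate direction lies in the row space of the
#' matrix recover at machine precision; the remainder inherit error from the
#' null space, bounded by the nonnegativity of the fit.
#'
#' @inheritParams sample_fractions
#' @param molecule molecule to survey.
#' @param n_trials number of forward-invert trials (default 5000).
#' @param seed RNG seed (all survey randomness flows from it).
#' @param na_correct survey the natural-abundance-augmented matrix instead of
#'   the pure 13C matrix (default \code{FALSE}: the survey is a property of
#'   the tracer-labeling map itself).
#' @param method solver, see \code{\link{solve_nnls}}.
#' @param matrix optionally a prebuilt \code{\link{mapping_matrix}}.
#' @return object of class \code{"isotopomer_survey"}: a data.frame with one
#'   row per labeling and columns \code{labeling}, \code{median}, \code{q025},
#'   \code{q975}, \code{bound} (the larger of |q025| and |q975|),
#'   \code{max_abs} and \code{identifiable}; the configuration is attached as
#'   attributes (\code{n_trials}, \code{seed}, \code{sampler},
#'   \code{constraint}, \code{method}, \code{errors}: the full trials x
#'   labelings signed-error matrix).
#' @examples
#' sv <- run_survey("aspartate", n_trials = 50, sampler = "beta_stick", seed = 1)
#' head(as.data.frame(sv))
#' @export
run_survey <- function(molecule = "glutamate", n_trials = 5000,
                       sampler = c("uniform_simplex", "beta_stick"),
                       constraint = c("none", "acetylcoa"),
                       limit = 0.02, major = "11", seed = 20230822,
                       na_correct = FALSE, method = "hybrid", matrix = NULL) {
  sampler <- match.arg(sampler)
  constraint <- match.arg(constraint)
  stopifnot(n_trials >= 1)
  mol <- as_molecule(molecule)
  A <- if (is.null(matrix)) mapping_matrix(mol, na_correct = na_correct) else matrix
  set.seed(seed)
  X <- sample_fractions(n_trials, mol, sampler, constraint, limit, major)
  E <- matrix(NA_real_, n_trials, ncol(A), dimnames = list(NULL, colnames(A)))
  failed <- 0L
  for (t in seq_len(n_trials)) {
    b <- normalize_intensities(as.numeric(unclass(A) %*% X[t, ]), A)
    sol <- tryCatch(solve_nnls(b, A, method = method), error = function(e) NULL)
    if (is.null(sol)) { failed <- failed + 1L; next }
    E[t, ] <- sol$fractions - X[t, ]
  }
  if (failed > 0L) {
    warning(failed, " trial(s) failed to solve and were excluded")
    E <- E[stats::complete.cases(E), , drop = FALSE]
  }
  ids <- identifiable_set(A)
  q <- apply(E, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  out <- data.frame(labeling = colnames(A),
                    median = q[2, ], q025 = q[1, ], q975 = q[3, ],
                    bound = pmax(abs(q[1, ]), abs(q[3, ])),
                    max_abs = apply(abs(E), 2, max),
                    identifiable = ids$flag,
                    row.names = NULL)
  structure(out, class = c("isotopomer_survey", "data.frame"),
            molecule = mol$name, n_trials = nrow(E), seed = seed,
            sampler = sampler, constraint = constraint, limit = limit,
            major = major, method = method, n_failed = failed, errors = E)
}

#' @export
print.isotopomer_survey <- function(x, ...) {
  cat(sprintf("<isotopomer_survey> %s: %d trials, sampler %s, constraint %s, seed %d\n",
              attr(x, "molecule"), attr(x, "n_trials"), attr(x, "sampler"),
              attr(x, "constraint"), attr(x, "seed")))
  cat(sprintf("identifiable: %d of %d (max abs error %.3g)\n",
              sum(x$identifiable), nrow(x), max(x$max_abs[x$identifiable])))
  if (any(!x$identifiable)) {
    cat(sprintf("under-determined: %d (95%% bound up to %.3g)\n",
                sum(!x$identifiable), max(x$bound[!x$identifiable])))
  }
  df <- as.data.frame(x)
  df[c("median", "q025", "q975", "bound", "max_abs")] <-
    lapply(df[c("median", "q025", "q975", "bound", "max_abs")], signif, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export a survey result as CSV
#'
#' Writes the per-labeling error statistics with the survey configuration in
#' commented header lines.
#'
#' @param x an \code{\link{run_survey}} result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_survey_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mrmiso survey: molecule=%s n_trials=%d sampler=%s constraint=%s limit=%g major=%s seed=%d method=%s",
                     attr(x, "molecule"), attr(x, "n_trials"), attr(x, "sampler"),
                     attr(x, "constraint"), attr(x, "limit"), attr(x, "major"),
                     attr(x, "seed"), attr(x, "method")), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}
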