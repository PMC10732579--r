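#' Normalize MRM areas within transition families
#'
#' Measured peak areas are only comparable within a transition family (one
#' precursor/product pair and its labeled forms, acquired in one polarity), so
#' the fit works on per-family intensity fractions: each unmasked area divided
#' by its family total. A family whose unmasked total is zero carries no
#' information and is excluded with a warning.
#'
#' @param areas numeric vector of areas aligned with the rows of \code{A};
#'   \code{NA} marks a masked (unmeasured) transition.
#' @param A a \code{\link{mapping_matrix}}.
#' @return numeric vector of per-family fractions (\code{NA} where masked or
#'   where the whole family was dropped).
#' @export
normalize_intensities <- function(areas, A) {
  fam <- attr(A, "family")
  stopifnot(length(areas) == nrow(A))
  if (any(areas < 0, na.rm = TRUE)) stop("areas must be nonnegative")
  out <- rep(NA_real_, length(areas))
  for (f in unique(fam)) {
    idx <- which(fam == f & !is.na(areas))
    if (!length(idx)) next
    tot <- sum(areas[idx])
    if (tot == 0) {
      warning("family ", f, " has zero total area; excluded from the fit")
      next
    }
    out[idx] <- areas[idx] / tot
  }
  if (all(is.na(out))) stop("no family with usable signal")
  out
}

#' Bounded nonnegative least-squares deconvolution of one intensity vector
#'
#' Solves \eqn{\min_x \|Ax - b\|^2} subject to \eqn{0 \le x \le 1} over the
#' unmasked rows of the mapping matrix, then normalizes the solution to a
#' fraction vector. Three solution methods are available:
#' \describe{
#'   \item{\code{"hybrid"} (default)}{active-set nonnegative least squares
#'     polished by QR iterative refinement on the passive set (this pins the
#'     identifiable, row-space part of the solution at machine precision),
#'     with the null-space component replaced by that of the
#'     coordinate-descent solution. The data cannot determine the null-space
#'     component; coordinate descent's implicit selection spreads it across
#'     the under-determined isotopomers and has the smallest simulation error
#'     of the candidate solvers.}
#'   \item{\code{"glmnet"}}{unregularized bounded coordinate descent
#'     (\code{lambda = 0}, \code{lower.limits = 0}, \code{upper.limits = 1},
#'     \code{intercept = FALSE}, \code{thresh = 1e-30}).}
#'   \item{\code{"lawson-hanson"}}{active-set NNLS
#'     (\code{pracma::lsqnonneg}) with QR refinement.}
#' }
#' The fraction vector is the raw solution divided by its sum; the division
#' is skipped when the sum is already 1 to machine precision, where it would
#' only inject rounding.
#'
#' @param b numeric vector of per-family intensity fractions aligned with the
#'   rows of \code{A}; \code{NA} entries are treated as masked.
#' @param A a \code{\link{mapping_matrix}}.
#' @param method solver, see Details.
#' @param thresh coordinate-descent convergence threshold.
#' @return list with \code{fractions} (normalized, canonical labeling order),
#'   \code{raw} (before normalization), \code{residual_norm},
#'   \code{n_masked}, and \code{method}.
#' @examples
#' A <- mapping_matrix(glutamate())
#' b <- as.numeric(A %*% (labeling_strings(glutamate()) == "11111"))
#' fit <- solve_nnls(normalize_intensities(b, A), A)
#' fit$fractions["11111"]
#' @export
solve_nnls <- function(b, A, method = c("hybrid", "glmnet", "lawson-hanson"),
                       thresh = 1e-30) {
  method <- match.arg(method)
  stopifnot(length(b) == nrow(A))
  if (any(b < 0, na.rm = TRUE)) stop("b must be nonnegative")
  keep <- !is.na(b)
  As <- unclass(A)[keep, , drop = FALSE]
  bs <- b[keep]
  x <- switch(method,
    "glmnet" = cd_solve(As, bs, thresh),
    "lawson-hanson" = refine_activeset(As, bs, pracma::lsqnonneg(As, bs)$x),
    "hybrid" = {
      xa <- refine_activeset(As, bs, pracma::lsqnonneg(As, bs)$x)
      xg <- cd_solve(As, bs, thresh)
      s <- svd(As)
      tol <- max(dim(As)) * .Machine$double.eps * s$d[1]
      Nv <- s$v[, s$d <= tol, drop = FALSE]
      xa + as.numeric(Nv %*% crossprod(Nv, xg - xa))
    })
  x[x < 0] <- 0
  x[x > 1] <- 1
  raw <- x
  s <- sum(x)
  fractions <- if (abs(s - 1) > 1e-12) x / s else x
  names(raw) <- names(fractions) <- colnames(A)
  list(fractions = fractions, raw = raw,
       residual_norm = sqrt(sum((As %*% raw - bs)^2)),
       n_masked = sum(!keep), method = method)
}

# coordinate-descent bounded least squares (glmnet with the settings quoted
# in the text: no penalty, no intercept, coefficients in [0, 1])
cd_solve <- function(As, bs, thresh = 1e-30) {
  f <- glmnet::glmnet(As, bs, lambda = 0, lower.limits = 0, upper.limits = 1,
                      intercept = FALSE, standardize = FALSE, thresh = thresh)
  as.numeric(stats::coef(f))[-1]
}

# iterative refinement of an active-set solution: re-solve the least-squares
# problem on the positive support by QR, repeat; falls back to a pseudoinverse
# step if the support becomes rank deficient
refine_activeset <- function(As, bs, x, iters = 3L) {
  for (k in seq_len(iters)) {
    P <- which(x > 1e-12)
    if (!length(P)) break
    r <- bs - As %*% x
    dz <- tryCatch(qr.solve(qr(As[, P, drop = FALSE]), r),
                   error = function(e) {
                     as.numeric(pracma::pinv(As[, P, drop = FALSE]) %*% r)
                   })
    x[P] <- x[P] + as.numeric(dz)
    x[x < 0] <- 0
  }
  x
}

#' Fit isotopomer distributions to MRM intensity data
#'
#' The main fitting interface: takes a long-format table of MRM peak areas
#' (one row per sample and ion pair), matches rows to the configured
#' transitions by nominal Q1/Q3 m/z, normalizes areas within transition
#' families, and deconvolves each sample into a positional isotopomer
#' distribution by bounded nonnegative least squares against the mapping
#' matrix.
#'
#' Transitions configured in the matrix but absent from a sample's table are
#' masked (absence is not a measurement); a zero area, in contrast, is a
#' measurement and enters the fit. Table rows matching no configured
#' transition are dropped with a message.
#'
#' @param intensities a data.frame with columns \code{sample_id}, \code{Q1},
#'   \code{Q3}, \code{area} (see \code{\link{read_intensity_csv}}), or a
#'   numeric matrix/vector of areas whose rownames/names are matrix row labels
#'   (\code{"<family>:<Q1>/<Q3>"}).
#' @param molecule a \code{molecule_spec} or molecule name. Ignored when
#'   \code{matrix} is supplied.
#' @param na_correct deconvolve against the natural-abundance-augmented
#'   matrix (default) or the pure 13C matrix.
#' @param matrix optionally, a prebuilt \code{\link{mapping_matrix}}.
#' @param method solver passed to \code{\link{solve_nnls}}.
#' @param mask character vector of transition row labels to exclude from every
#'   sample (e.g. a chromatographically overlapped ion pair).
#' @param mz_window m/z half-window for matching table rows to nominal
#'   transitions.
#' @return object of class \code{"isotopomer_fit"} with methods
#'   \code{print}, \code{summary}, \code{coef}, \code{fitted},
#'   \code{residuals}, \code{predict}, \code{plot} and \code{simulate}.
#'   \code{coef()} returns the samples x labelings fraction matrix.
#' @examples
#' glu <- glutamate()
#' A <- mapping_matrix(glu, na_correct = TRUE)
#' truth <- setNames(numeric(32), labeling_strings(glu))
#' truth[c("00000", "11111")] <- c(0.4, 0.6)
#' tab <- simulate_mrm(truth, A)
#' fit <- isotopomer_fit(tab, glu)
#' round(coef(fit)[, c("00000", "11111")], 6)
#' @export
isotopomer_fit <- function(intensities, molecule = "glutamate",
                           na_correct = TRUE, matrix = NULL,
                           method = c("hybrid", "glmnet", "lawson-hanson"),
                           mask = NULL, mz_window = 0.5) {
  method <- match.arg(method)
  A <- if (is.null(matrix)) {
    mapping_matrix(as_molecule(molecule), na_correct = na_correct)
  } else matrix
  mol <- attr(A, "molecule")
  areas <- align_intensities(intensities, A, mz_window)
  if (!is.null(mask)) {
    bad <- setdiff(mask, rownames(A))
    if (length(bad)) stop("unknown transitions in mask: ", paste(bad, collapse = ", "))
    areas[rownames(A) %in% mask, ] <- NA_real_
  }
  nsamp <- ncol(areas)
  labs <- colnames(A)
  coefs <- raw <- matrix(NA_real_, nsamp, length(labs),
                         dimnames = list(colnames(areas), labs))
  bmat <- matrix(NA_real_, nrow(A), nsamp,
                 dimnames = list(rownames(A), colnames(areas)))
  resid_norm <- setNames(numeric(nsamp), colnames(areas))
  n_masked <- setNames(integer(nsamp), colnames(areas))
  for (s in seq_len(nsamp)) {
    b <- normalize_intensities(areas[, s], A)
    sol <- solve_nnls(b, A, method = method)
    coefs[s, ] <- sol$fractions
    raw[s, ] <- sol$raw
    bmat[, s] <- b
    resid_norm[s] <- sol$residual_norm
    n_masked[s] <- sol$n_masked
  }
  structure(list(coefficients = coefs, raw = raw, b = bmat,
                 residual_norm = resid_norm, n_masked = n_masked,
                 matrix = A, molecule = mol, method = method,
                 call = match.call()),
            class = "isotopomer_fit")
}

# coerce long table / matrix / vector into an areas matrix aligned with A's rows
align_intensities <- function(intensities, A, mz_window = 0.5) {
  if (is.numeric(intensities) && is.null(dim(intensities))) {
    intensities <- as.matrix(intensities)
    colnames(intensities) <- "sample1"
  }
  if (is.matrix(intensities)) {
    if (is.null(rownames(intensities))) {
      stop("a numeric intensity matrix needs transition row names")
    }
    unknown <- setdiff(rownames(intensities), rownames(A))
    if (length(unknown)) {
      message("dropping ", length(unknown), " rows matching no configured transition")
    }
    out <- matrix(NA_real_, nrow(A), ncol(intensities),
                  dimnames = list(rownames(A), colnames(intensities)))
    hit <- intersect(rownames(intensities), rownames(A))
    out[hit, ] <- intensities[hit, , drop = FALSE]
    return(out)
  }
  df <- as.data.frame(intensities)
  names(df) <- tolower(names(df))
  need <- c("sample_id", "q1", "q3", "area")
  if (!all(need %in% names(df))) {
    stop("intensity table must have columns sample_id, Q1, Q3, area")
  }
  if (!is.numeric(df$area)) stop("non-numeric area column")
  tr <- attr(A, "transitions")
  ridx <- mapply(function(q1, q3) {
    hit <- which(abs(tr$q1 - q1) <= mz_window & abs(tr$q3 - q3) <= mz_window)
    if (length(hit) == 1L) hit else NA_integer_
  }, df$q1, df$q3)
  if (anyNA(ridx)) {
    message("dropping ", sum(is.na(ridx)),
            " rows matching no configured transition")
  }
  df <- df[!is.na(ridx), , drop = FALSE]
  ridx <- ridx[!is.na(ridx)]
  samples <- unique(df$sample_id)
  out <- matrix(NA_real_, nrow(A), length(samples),
                dimnames = list(rownames(A), samples))
  dup <- duplicated(cbind(df$sample_id, ridx))
  if (any(dup)) {
    warning(sum(dup), " duplicate (sample, transition) rows summed")
  }
  for (k in seq_len(nrow(df))) {
    s <- match(df$sample_id[k], samples)
    cur <- out[ridx[k], s]
    out[ridx[k], s] <- if (is.na(cur)) df$area[k] else cur + df$area[k]
  }
  out
}

#' @export
print.isotopomer_fit <- function(x, ...) {
  cat(sprintf("<isotopomer_fit> %s, %d sample(s), %s matrix, solver \"%s\"\n",
              x$molecule$name, nrow(x$coefficients),
              if (attr(x$matrix, "na_corrected")) "natural-abundance-corrected"
              else "pure-13C", x$method))
  cat("residual norms:\n")
  print(signif(x$residual_norm, 4))
  invisible(x)
}

#' @export
coef.isotopomer_fit <- function(object, ...) object$coefficients

#' @export
fitted.isotopomer_fit <- function(object, ...) {
  pred <- unclass(object$matrix) %*% t(object$raw)
  pred[is.na(object$b)] <- NA_real_
  # forward model of the raw solution, renormalized where rows were masked
  fam <- attr(object$matrix, "family")
  for (s in seq_len(ncol(pred))) {
    for (f in unique(fam)) {
      idx <- which(fam == f & !is.na(pred[, s]))
      if (length(idx) && sum(pred[idx, s]) > 0) {
        pred[idx, s] <- pred[idx, s] / sum(pred[idx, s]) *
          sum(object$b[idx, s])
      }
    }
  }
  pred
}

#' @export
residuals.isotopomer_fit <- function(object, ...) {
  object$b - fitted(object)
}

#' @param object an \code{isotopomer_fit}.
#' @param newdata optional new intensity data (same formats as
#'   \code{isotopomer_fit}); when omitted the fitted per-family intensity
#'   fractions are returned.
#' @rdname isotopomer_fit
#' @export
predict.isotopomer_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  refit <- isotopomer_fit(newdata, matrix = object$matrix,
                          method = object$method)
  coef(refit)
}

#' @export
summary.isotopomer_fit <- function(object, min_fraction = 0.005, ...) {
  structure(list(fit = object, min_fraction = min_fraction),
            class = "summary.isotopomer_fit")
}

#' @export
print.summary.isotopomer_fit <- function(x, ...) {
  object <- x$fit
  print(object)
  for (s in rownames(object$coefficients)) {
    fr <- object$coefficients[s, ]
    fr <- sort(fr[fr >= x$min_fraction], decreasing = TRUE)
    cat(sprintf("\n%s (fractions >= %.3g):\n", s, x$min_fraction))
    print(round(fr, 4))
  }
  invisible(x)
}

#' @export
plot.isotopomer_fit <- function(x, sample = 1, ...) {
  fr <- x$coefficients[sample, ]
  graphics::barplot(fr, las = 2, cex.names = 0.6,
                    ylab = "isotopomer fraction",
                    main = rownames(x$coefficients)[sample], ...)
  invisible(x)
}

#' @param nsim number of replicate tables to simulate.
#' @param seed RNG seed.
#' @param total_area per-family total area of the simulated tables.
#' @param rsd multiplicative relative standard deviation of the noise model.
#' @rdname isotopomer_fit
#' @export
simulate.isotopomer_fit <- function(object, nsim = 1, seed = NULL,
                                    total_area = 1e6, rsd = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    tabs <- lapply(rownames(object$coefficients), function(s) {
      tab <- simulate_mrm(object$coefficients[s, ], object$matrix,
                          noise = noise_model(rsd = rsd),
                          total_area = total_area, sample_id = s)
      tab
    })
    out[[k]] <- do.call(rbind, tabs)
  }
  if (nsim == 1) out[[1]] else out
}
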