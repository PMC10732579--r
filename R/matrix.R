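#' Mass-shift distribution from natural isotope abundance
#'
#' Probability distribution of the nominal mass shift of an ion caused by
#' naturally occurring heavy isotopes (2H, 13C, 15N, 17O, 18O), computed as
#' the convolution of independent per-atom distributions. On a unit-resolution
#' instrument every +1 channel is indistinguishable, so all isotopes collapse
#' onto integer shifts. Carbons that carry a deliberate 13C label are excluded
#' from the natural-13C statistics.
#'
#' @param formula elemental composition: named integer vector (see
#'   \code{\link{parse_formula}}) or formula string.
#' @param excluded_carbons number of deliberately 13C-labeled carbons to
#'   exclude from the natural-abundance binomial for carbon.
#' @param abundances an \code{\link{isotope_abundances}} table.
#' @param max_shift truncate the returned distribution at this shift. The
#'   untruncated distribution sums to 1; truncation drops the (tiny) tail mass.
#' @return numeric vector of probabilities, element k is the probability of
#'   shift k - 1 (names give the shifts).
#' @examples
#' natural_shift_distribution("C", 0)        # c(0.98918, 0.01082)
#' natural_shift_distribution("C5H8NO4", 0)[1]
#' @export
natural_shift_distribution <- function(formula, excluded_carbons = 0,
                                       abundances = isotope_abundances(),
                                       max_shift = Inf) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (excluded_carbons < 0) stop("excluded_carbons must be nonnegative")
  if (excluded_carbons > formula_count(formula, "C")) {
    stop("excluded_carbons exceeds the carbon count of the formula")
  }
  d <- 1
  for (el in names(formula)) {
    n <- formula[[el]]
    if (el == "C") n <- n - excluded_carbons
    if (n == 0L) next
    pe <- abundances[[el]]
    if (is.null(pe)) stop("abundance table is missing element ", el)
    for (k in seq_len(n)) d <- convolve_dist(d, pe)
  }
  d <- d[seq_len(min(length(d), max_shift + 1))]
  names(d) <- seq_along(d) - 1L
  d
}

convolve_dist <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (k in seq_along(b)) {
    idx <- seq_along(a) + k - 1L
    out[idx] <- out[idx] + a * b[k]
  }
  out
}

#' Build the isotopomer-to-ion-pair mapping matrix
#'
#' Constructs the linear map A from isotopomer fractions to per-family
#' transition intensity fractions. Rows are MRM ion pairs (grouped in family
#' blocks), columns are the 2^n labelings in canonical lexicographic order.
#' With \code{na_correct = FALSE} each labeling contributes its component
#' weights at the ion pairs given by \code{\link{transition_signature}}. With
#' \code{na_correct = TRUE}, natural-abundance mass shifts of the product ion
#' and of the neutral loss are convolved in:
#' \deqn{A[(i,j), L] = \sum_f w_f \, P_{prod}(j - j_L) \, P_{loss}((i - i_L) - (j - j_L))}
#' where \eqn{(i_L, j_L)} is the pure-label shift of labeling L under fragment
#' f, and the natural distributions exclude the deliberately labeled carbons.
#' Rows are enumerated to \code{max_shift} and all-zero rows dropped; within
#' every family block each column is renormalized to sum to 1, so truncated
#' tail mass is redistributed rather than lost (matching the fitting of
#' per-family normalized intensity fractions).
#'
#' @param molecule a \code{molecule_spec} or molecule name.
#' @param na_correct logical: augment the matrix with natural-abundance
#'   shifts?
#' @param abundances isotope abundance table used when \code{na_correct} is
#'   \code{TRUE}.
#' @param max_shift largest precursor shift enumerated for the augmented
#'   matrix; default \code{n_carbons + 3}.
#' @return object of class \code{"mapping_matrix"}: a numeric matrix with
#'   attributes \code{molecule}, \code{na_corrected}, \code{transitions}
#'   (data.frame family/i/j/q1/q3) and \code{family} (family id per row).
#'   Row names are \code{"<family>:<Q1>/<Q3>"}; column names are labeling
#'   strings.
#' @examples
#' A <- mapping_matrix(glutamate())
#' dim(A)            # 56 ion pairs x 32 isotopomers
#' matrix_rank(A)    # 28
#' @export
mapping_matrix <- function(molecule, na_correct = FALSE,
                           abundances = isotope_abundances(),
                           max_shift = NULL) {
  mol <- as_molecule(molecule)
  n <- mol$n_carbons
  if (!na_correct) {
    abundances <- no_isotope_abundances()
    if (is.null(max_shift)) max_shift <- n
  } else {
    if (is.null(max_shift)) max_shift <- n + 3L
    if (max_shift < n) stop("max_shift must be at least n_carbons")
  }
  L <- enumerate_labelings(mol)
  nl <- nrow(L)
  blocks <- vector("list", length(mol$families))
  tinfo <- vector("list", length(mol$families))
  for (fi in seq_along(mol$families)) {
    fam <- mol$families[[fi]]
    grid <- expand.grid(j = 0:max_shift, i = 0:max_shift)
    grid <- grid[grid$j <= grid$i, c("i", "j")]
    grid <- grid[order(grid$i, grid$j), ]
    M <- matrix(0, nrow(grid), nl)
    for (cmp in fam$components) {
      loss <- subtract_formula(fam$precursor_formula, cmp$product_formula)
      iL <- rowSums(L)
      jL <- rowSums(L[, cmp$carbons, drop = FALSE])
      for (col in seq_len(nl)) {
        dp <- natural_shift_distribution(cmp$product_formula, jL[col],
                                         abundances, max_shift)
        dl <- natural_shift_distribution(loss, iL[col] - jL[col],
                                         abundances, max_shift)
        for (a in seq_along(dp) - 1L) {
          if (dp[a + 1L] == 0) next
          for (b in seq_along(dl) - 1L) {
            if (dl[b + 1L] == 0) next
            i <- iL[col] + a + b
            j <- jL[col] + a
            if (i > max_shift) next
            r <- which(grid$i == i & grid$j == j)
            M[r, col] <- M[r, col] + cmp$weight * dp[a + 1L] * dl[b + 1L]
          }
        }
      }
    }
    keep <- rowSums(M) > 1e-14
    M <- M[keep, , drop = FALSE]
    g <- grid[keep, , drop = FALSE]
    M <- sweep(M, 2, colSums(M), "/")
    rownames(M) <- sprintf("%s:%d/%d", fam$id, fam$q1 + g$i, fam$q3 + g$j)
    blocks[[fi]] <- M
    tinfo[[fi]] <- data.frame(family = fam$id, i = g$i, j = g$j,
                              q1 = fam$q1 + g$i, q3 = fam$q3 + g$j,
                              row.names = NULL, stringsAsFactors = FALSE)
  }
  A <- do.call(rbind, blocks)
  colnames(A) <- rownames(L)
  transitions <- do.call(rbind, tinfo)
  structure(A,
            molecule = mol,
            na_corrected = na_correct,
            transitions = transitions,
            family = transitions$family,
            class = c("mapping_matrix", "matrix", "array"))
}

#' @export
print.mapping_matrix <- function(x, ...) {
  mol <- attr(x, "molecule")
  cat(sprintf("<mapping_matrix> %s, %d ion pairs x %d isotopomers (%s), rank %d\n",
              mol$name, nrow(x), ncol(x),
              if (attr(x, "na_corrected")) "natural-abundance augmented" else "pure 13C",
              matrix_rank(x)))
  invisible(x)
}

#' Numerical rank of a mapping matrix
#'
#' Rank by singular value thresholding: singular values below
#' \code{max(dim(A)) * eps * sigma_1} count as zero.
#'
#' @param A a matrix.
#' @return integer rank.
#' @export
matrix_rank <- function(A) {
  d <- svd(unclass(A), nu = 0, nv = 0)$d
  sum(d > max(dim(A)) * .Machine$double.eps * d[1])
}

# cached SVD-derived pieces used by the solver; recomputed per matrix object
matrix_decomposition <- function(A) {
  s <- svd(unclass(A))
  tol <- max(dim(A)) * .Machine$double.eps * s$d[1]
  r <- sum(s$d > tol)
  list(svd = s, tol = tol, rank = r,
       # Moore-Penrose pseudoinverse (row-space inverse)
       pinv = s$v[, seq_len(r), drop = FALSE] %*%
         (t(s$u[, seq_len(r), drop = FALSE]) / s$d[seq_len(r)]),
       null = s$v[, -seq_len(r), drop = FALSE])
}

#' Identifiable and non-identifiable isotopomers of a mapping matrix
#'
#' An isotopomer is identifiable when its coordinate direction lies in the row
#' space of the mapping matrix: its fraction is then determined exactly by
#' noiseless data. Non-identifiable isotopomers span the null space and can
#' only be pinned down by the nonnegativity of the fit or by prior constraints
#' on the labeling pattern.
#'
#' @param A a \code{\link{mapping_matrix}}.
#' @param tol tolerance on the norm of the component of the coordinate
#'   direction outside the row space.
#' @return list with character vectors \code{identifiable} and
#'   \code{non_identifiable}, and the logical vector \code{flag} in column
#'   order.
#' @examples
#' ids <- identifiable_set(mapping_matrix(glutamate()))
#' length(ids$identifiable)  # 18
#' @export
identifiable_set <- function(A, tol = 1e-8) {
  dec <- matrix_decomposition(A)
  Vr <- dec$svd$v[, seq_len(dec$rank), drop = FALSE]
  flag <- vapply(seq_len(ncol(A)), function(k) {
    e <- numeric(ncol(A)); e[k] <- 1
    r <- e - Vr %*% Vr[k, ]                # residual outside the row space
    sqrt(sum(r^2)) < tol
  }, logical(1))
  names(flag) <- colnames(A)
  list(identifiable = colnames(A)[flag],
       non_identifiable = colnames(A)[!flag],
       flag = flag)
}

#' Export a mapping matrix as CSV
#'
#' Writes the matrix with ion-pair row labels and labeling-string column
#' labels.
#'
#' @param A a \code{\link{mapping_matrix}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_csv <- function(A, path) {
  df <- data.frame(transition = rownames(A), unclass(A), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
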