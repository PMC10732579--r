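#' Aggregate an isotopomer distribution into 13C NMR multiplet components
#'
#' A 13C nucleus in a 1D NMR spectrum splits by one-bond coupling to labeled
#' chain neighbours: singlet (no labeled neighbour), one doublet per labeled
#' neighbour side, and a doublet-of-doublets/quartet when both neighbours are
#' labeled. Every isotopomer with carbon k labeled contributes to exactly one
#' component of carbon k's multiplet, so the full positional distribution
#' aggregates losslessly into the multiplet fractions a 13C NMR analysis
#' reports.
#'
#' @param dist named fraction vector over all labelings (canonical order), or
#'   a one-row slice of \code{coef(isotopomer_fit)}.
#' @param molecule molecule of the distribution (only used for validation;
#'   inferred from the vector length when omitted).
#' @return object of class \code{"multiplet_summary"}: a list with
#'   \code{total} (per-carbon labeled fraction, e.g. \code{Glu4}) and
#'   \code{components} (per carbon, the fractions of S, D (by neighbour side)
#'   and Q components, summing to the carbon total).
#' @examples
#' d <- setNames(numeric(32), labeling_strings(5))
#' d["00111"] <- 1
#' multiplet_summary(d)$components$C4  # all quartet
#' @export
multiplet_summary <- function(dist, molecule = NULL) {
  dist <- as_distribution(dist, molecule)
  n <- as.integer(round(log2(length(dist))))
  L <- enumerate_labelings(n)
  prefix <- if (n == 5L) "Glu" else if (n == 4L) "Asp" else "C"
  total <- setNames(numeric(n), paste0("C", seq_len(n)))
  comps <- vector("list", n)
  names(comps) <- paste0("C", seq_len(n))
  for (k in seq_len(n)) {
    lab <- L[, k] == 1L
    total[k] <- sum(dist[lab])
    lo <- if (k > 1L) L[, k - 1L] == 1L else rep(FALSE, nrow(L))
    hi <- if (k < n) L[, k + 1L] == 1L else rep(FALSE, nrow(L))
    cmp <- c(S = sum(dist[lab & !lo & !hi]))
    if (k > 1L) cmp[sprintf("D%d%d", k - 1L, k)] <- sum(dist[lab & lo & !hi])
    if (k < n) cmp[sprintf("D%d%d", k, k + 1L)] <- sum(dist[lab & !lo & hi])
    if (k > 1L && k < n) cmp["Q"] <- sum(dist[lab & lo & hi])
    comps[[k]] <- cmp
  }
  structure(list(total = total, components = comps, prefix = prefix),
            class = "multiplet_summary")
}

#' @export
print.multiplet_summary <- function(x, ...) {
  cat("<multiplet_summary>\n")
  for (k in seq_along(x$total)) {
    nm <- names(x$total)[k]
    cat(sprintf("  %s%s total %.4f | %s\n", x$prefix, substring(nm, 2),
                x$total[k],
                paste(sprintf("%s %.4f", names(x$components[[k]]),
                              x$components[[k]]), collapse = "  ")))
  }
  invisible(x)
}

as_distribution <- function(dist, molecule = NULL, tol = 1e-6) {
  if (is.matrix(dist)) {
    if (nrow(dist) != 1L) stop("supply a single distribution (one row)")
    dist <- dist[1, ]
  }
  n <- as.integer(round(log2(length(dist))))
  if (2^n != length(dist)) stop("distribution length must be a power of 2")
  if (!is.null(molecule)) {
    mol <- as_molecule(molecule)
    if (mol$n_carbons != n) stop("distribution length does not match molecule")
  }
  if (is.null(names(dist))) names(dist) <- labeling_strings(n)
  dist <- dist[labeling_strings(n)]
  if (anyNA(dist) || any(dist < -1e-12)) stop("invalid distribution")
  dist
}

#' TCA-cycle readouts from isotopomer distributions
#'
#' Closed-form metabolic indices computed from positional isotopomer
#' fractions.
#'
#' \code{fc3_nmr} is the NMR-style estimator of F_C3, the fraction of the
#' acetyl-CoA pool feeding citrate synthase that is 13C-labeled on both
#' carbons: \code{Glu4Q * (Glu4 / Glu3)}, with Glu4Q the quartet fraction of
#' glutamate C4 and Glu4/Glu3 the ratio of total labeled C4 to total labeled
#' C3.
#'
#' \code{fc3_direct} estimates the same quantity directly from two glutamate
#' isotopomers: \code{glu11011 / (glu11000 + glu11011)}; both arise from
#' oxaloacetate 1101-pattern carbons, differing only in whether the condensing
#' acetyl-CoA carried label.
#'
#' \code{anaplerosis} is the relative anaplerotic flux
#' \code{y = Glu4/Glu3 - 1}: carbon entering the cycle other than through
#' citrate synthase dilutes C3 relative to C4.
#'
#' @param x for \code{fc3_nmr} and \code{anaplerosis}, a
#'   \code{\link{multiplet_summary}} or a glutamate distribution (coerced);
#'   for \code{fc3_direct}, a glutamate distribution.
#' @return a single numeric value.
#' @examples
#' d <- setNames(numeric(32), labeling_strings(5))
#' d[c("11011", "11000", "00000")] <- c(0.08, 0.02, 0.90)
#' fc3_direct(d)  # 0.8
#' @export
fc3_nmr <- function(x) {
  ms <- as_multiplet(x)
  g3 <- ms$total[["C3"]]; g4 <- ms$total[["C4"]]
  if (g3 <= 0) stop("Glu3 total is zero; F_C3 undefined")
  if (g4 <= 0) stop("Glu4 total is zero; F_C3 undefined")
  q4 <- ms$components$C4[["Q"]] / g4
  q4 * g4 / g3
}

as_multiplet <- function(x) {
  if (inherits(x, "multiplet_summary")) x else multiplet_summary(x)
}

#' @rdname fc3_nmr
#' @export
fc3_direct <- function(x) {
  d <- as_distribution(x)
  if (length(d) != 32L) stop("fc3_direct needs a glutamate distribution")
  den <- d[["11000"]] + d[["11011"]]
  if (den <= 0) stop("glu11000 + glu11011 is zero; F_C3 undefined")
  d[["11011"]] / den
}

#' @rdname fc3_nmr
#' @export
anaplerosis <- function(x) {
  ms <- as_multiplet(x)
  g3 <- ms$total[["C3"]]
  if (g3 <= 0) stop("Glu3 total is zero; anaplerosis undefined")
  ms$total[["C4"]] / g3 - 1
}

#' Pyruvate carboxylase activity contrast
#'
#' With acetyl-CoA as the only labeled carbon source the four m+3 aspartate
#' isotopomers 1110, 0111, 1101, 1011 are produced equally (succinate and
#' fumarate are symmetric). Pyruvate carboxylase feeds oxaloacetate 1110
#' (scrambling to 0111) directly, so the excess
#' \code{(asp1110 + asp0111) - (asp1101 + asp1011)} reports PC activity.
#' The corroborating glutamate contrast \code{glu01111 - glu10111} is returned
#' when a glutamate distribution is supplied.
#'
#' @param asp aspartate distribution (16 fractions, canonical order).
#' @param glu optional glutamate distribution (32 fractions).
#' @return named numeric: \code{pc_index} and, if \code{glu} given,
#'   \code{glu_contrast}.
#' @export
pc_index <- function(asp, glu = NULL) {
  d <- as_distribution(asp)
  if (length(d) != 16L) stop("pc_index needs an aspartate distribution")
  out <- c(pc_index = (d[["1110"]] + d[["0111"]]) - (d[["1101"]] + d[["1011"]]))
  if (!is.null(glu)) {
    g <- as_distribution(glu)
    if (length(g) != 32L) stop("glu must be a glutamate distribution")
    out["glu_contrast"] <- g[["01111"]] - g[["10111"]]
  }
  out
}

#' Fumarate hydratase symmetrization contrast
#'
#' Passage through symmetric fumarate equalizes mirror-image aspartate
#' isotopomers. An excess of aspartate 1110 over 0111 therefore marks absent
#' or incomplete fumarate scrambling (e.g. FH-deficient cells) when the pair
#' is fed asymmetrically (PC produces 1110 only). The PDH-derived pair
#' 1100/0011 is returned as companion contrast: it is expected symmetric
#' whenever the label reaches oxaloacetate through the cycle.
#'
#' @param asp aspartate distribution.
#' @return named numeric: \code{fh_asymmetry} (asp1110 - asp0111) and
#'   \code{pdh_contrast} (asp1100 - asp0011).
#' @export
fh_asymmetry <- function(asp) {
  d <- as_distribution(asp)
  if (length(d) != 16L) stop("fh_asymmetry needs an aspartate distribution")
  c(fh_asymmetry = d[["1110"]] - d[["0111"]],
    pdh_contrast = d[["1100"]] - d[["0011"]])
}

#' Inner/outer balance of singly labeled aspartate
#'
#' Among the m+1 aspartate isotopomers, the fraction labeled on an outer
#' (carboxyl) carbon: \code{(asp1000 + asp0001) / (m+1 total)}. Carboxylation
#' with 13CO2 labels outer carbons only (balance 1), whereas multi-turn
#' oxidation of PDH-derived label distributes m+1 equally over all four
#' positions (balance 0.5).
#'
#' @param asp aspartate distribution.
#' @return fraction in [0, 1].
#' @export
m1_balance <- function(asp) {
  d <- as_distribution(asp)
  if (length(d) != 16L) stop("m1_balance needs an aspartate distribution")
  m1 <- d[["1000"]] + d[["0100"]] + d[["0010"]] + d[["0001"]]
  if (m1 <= 0) stop("no m+1 mass; balance undefined")
  (d[["1000"]] + d[["0001"]]) / m1
}

#' All TCA readouts for a pair of distributions
#'
#' Convenience wrapper computing every readout that the supplied
#' distributions admit.
#'
#' @param glu glutamate distribution, or \code{NULL}.
#' @param asp aspartate distribution, or \code{NULL}.
#' @return named numeric vector (metrics whose preconditions fail are
#'   returned as \code{NA}).
#' @export
tca_readout <- function(glu = NULL, asp = NULL) {
  out <- c()
  safely <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  if (!is.null(glu)) {
    ms <- multiplet_summary(glu)
    out <- c(out,
             fc3_eq1 = safely(fc3_nmr(ms)),
             fc3_eq2 = safely(fc3_direct(glu)),
             anaplerosis_y = safely(anaplerosis(ms)))
  }
  if (!is.null(asp)) {
    out <- c(out,
             pc_index = safely(unname(pc_index(asp)[1])),
             fh_asymmetry = safely(unname(fh_asymmetry(asp)[1])),
             m1_outer_fraction = safely(m1_balance(asp)))
  }
  if (!is.null(glu) && !is.null(asp)) {
    out["glu_pc_contrast"] <- safely(unname(pc_index(asp, glu)["glu_contrast"]))
  }
  out
}
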