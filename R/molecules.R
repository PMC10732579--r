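#' Parse an elemental formula string
#'
#' Converts a Hill-style formula such as \code{"C5H8NO4"} into a named integer
#' vector of element counts. Only single-letter capitalisation rules are
#' supported (an element is one capital letter optionally followed by
#' lowercase letters, then an optional count).
#'
#' @param x formula string, e.g. \code{"C2HO"}.
#' @return named integer vector of element counts.
#' @examples
#' parse_formula("C5H8NO4")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  m <- gregexpr("([A-Z][a-z]*)([0-9]*)", x)[[1]]
  parts <- regmatches(x, gregexpr("([A-Z][a-z]*)([0-9]*)", x))[[1]]
  if (sum(nchar(parts)) != nchar(x)) {
    stop("cannot parse formula: ", x)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- sub("^[A-Za-z]+", "", parts)
  n <- ifelse(n == "", 1L, as.integer(n))
  out <- tapply(n, el, sum)
  out <- setNames(as.integer(out), names(out))
  out[order(names(out))]
}

formula_count <- function(formula, element) {
  if (element %in% names(formula)) unname(formula[[element]]) else 0L
}

# elementwise difference a - b; errors if any count would go negative
subtract_formula <- function(a, b) {
  els <- union(names(a), names(b))
  r <- vapply(els, function(e) formula_count(a, e) - formula_count(b, e), integer(1))
  if (any(r < 0)) stop("neutral loss has negative element counts")
  r <- r[r > 0]
  r[order(names(r))]
}

#' Natural isotope abundance table
#'
#' Per-element probabilities of mass shifts caused by naturally occurring
#' heavy isotopes. Shift 0 is the monoisotopic species; oxygen carries both a
#' +1 (17O) and a +2 (18O) channel. Defaults: 2H 0.0156\%, 13C 1.082\%,
#' 15N 0.366\%, 17O 0.038\%, 18O 0.204\%.
#'
#' @param H,C,N,O per-element heavy-isotope abundances (fractions). \code{O}
#'   is length 2: \code{c(p17, p18)}.
#' @return object of class \code{"isotope_abundances"}: a named list with one
#'   numeric probability vector per element, indexed by mass shift 0, 1, (2).
#' @examples
#' isotope_abundances()          # default natural abundances
#' isotope_abundances(C = 0)     # switch off natural 13C
#' @export
isotope_abundances <- function(H = 0.000156, C = 0.01082, N = 0.00366,
                               O = c(0.00038, 0.00204)) {
  stopifnot(length(O) == 2L)
  tab <- list(
    H = c(1 - H, H),
    C = c(1 - C, C),
    N = c(1 - N, N),
    O = c(1 - sum(O), O[1], O[2])
  )
  for (el in names(tab)) {
    if (any(tab[[el]] < 0) || abs(sum(tab[[el]]) - 1) > 1e-9) {
      stop("abundances for ", el, " must be fractions summing to 1")
    }
  }
  structure(tab, class = "isotope_abundances")
}

#' Zeroed isotope abundance table
#'
#' All heavy-isotope abundances set to zero (every atom monoisotopic); with
#' this table the natural-abundance-augmented mapping matrix degenerates to
#' the pure 13C matrix.
#'
#' @return an \code{"isotope_abundances"} object.
#' @export
no_isotope_abundances <- function() {
  isotope_abundances(H = 0, C = 0, N = 0, O = c(0, 0))
}

new_family <- function(id, polarity, q1, q3, precursor_formula, components) {
  w <- vapply(components, function(cmp) cmp$weight, numeric(1))
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-9) {
    stop("component weights of family ", id, " must be in (0,1] and sum to 1")
  }
  for (cmp in components) {
    nc <- formula_count(cmp$product_formula, "C")
    if (nc != length(cmp$carbons)) {
      stop("family ", id, ": product formula carbon count (", nc,
           ") does not match retained carbons (", length(cmp$carbons), ")")
    }
  }
  structure(list(id = id, polarity = polarity, q1 = q1, q3 = q3,
                 precursor_formula = precursor_formula,
                 components = components),
            class = "transition_family")
}

component <- function(carbons, product_formula, weight) {
  list(carbons = as.integer(carbons),
       product_formula = if (is.character(product_formula)) parse_formula(product_formula) else product_formula,
       weight = weight)
}

#' Molecule definitions for isotopomer analysis
#'
#' \code{glutamate()} and \code{aspartate()} return the built-in molecule
#' specifications: carbon count, neutral formula, and the default MRM
#' transition families with their fragment carbon ranges, product-ion
#' elemental formulas and mixed-fragment weights. Carbons are numbered with
#' C1 the alpha-carboxyl carbon, matching the bit-string notation in which
#' \code{"11000"} denotes 13C at C1 and C2.
#'
#' Default glutamate families (precursor/product nominal m/z): 146/41 (C4-5),
#' 146/74 (C1-2), 146/102 (C1-4 : C2-5 mixed 19:1), 148/84 (C2-5) and 148/56
#' (C2-4 : C3-5 mixed 98:2). Default aspartate families: 134/88 (C2-4),
#' 134/74 (C1-2), 134/43 (C3-4) and 132/88 (C1-3 : C2-4 mixed 15:1).
#'
#' @param mix_102 two nonnegative numbers, the C1-4 : C2-5 ratio of the mixed
#'   146/102 fragment. Default \code{c(19, 1)}.
#' @param mix_56 the C2-4 : C3-5 ratio of the mixed 148/56 fragment,
#'   default \code{c(98, 2)}.
#' @param interference_41 weight in \code{[0, 1)} of a C2-4 (C3H5) fragment
#'   contributing to the 146/41 ion pair. Default 0: the ion pair that would
#'   reveal this interference is below the detection limit on a unit-resolution
#'   instrument, so the family is treated as pure C4-5 unless overridden.
#' @return object of class \code{"molecule_spec"}.
#' @examples
#' glutamate()
#' aspartate(mix_88 = c(15, 1))
#' @export
glutamate <- function(mix_102 = c(19, 1), mix_56 = c(98, 2),
                      interference_41 = 0) {
  stopifnot(interference_41 >= 0, interference_41 < 1)
  w102 <- mix_102 / sum(mix_102)
  w56 <- mix_56 / sum(mix_56)
  neg <- parse_formula("C5H8NO4")   # [M-H]- of C5H9NO4
  pos <- parse_formula("C5H10NO4")  # [M+H]+
  fam41 <- if (interference_41 > 0) {
    list(component(4:5, "C2HO", 1 - interference_41),
         component(2:4, "C3H5", interference_41))
  } else {
    list(component(4:5, "C2HO", 1))
  }
  families <- list(
    new_family("146/41", "-", 146, 41, neg, fam41),
    new_family("146/74", "-", 146, 74, neg, list(component(1:2, "C2H4NO2", 1))),
    new_family("146/102", "-", 146, 102, neg,
               list(component(1:4, "C4H8NO2", w102[1]),
                    component(2:5, "C4H8NO2", w102[2]))),
    new_family("148/84", "+", 148, 84, pos, list(component(2:5, "C4H6NO", 1))),
    new_family("148/56", "+", 148, 56, pos,
               list(component(2:4, "C3H6N", w56[1]),
                    component(3:5, "C3H4O", w56[2])))
  )
  new_molecule("glutamate", 5L, parse_formula("C5H9NO4"), families)
}

#' @rdname glutamate
#' @param mix_88 the C1-3 : C2-4 ratio of the mixed aspartate 132/88 fragment,
#'   default \code{c(15, 1)}.
#' @param frag_43 retained carbons of the 134/43 product ion, default
#'   \code{c(3, 4)} (configuration-overridable).
#' @export
aspartate <- function(mix_88 = c(15, 1), frag_43 = c(3, 4)) {
  w88 <- mix_88 / sum(mix_88)
  neg <- parse_formula("C4H6NO4")   # [M-H]- of C4H7NO4
  pos <- parse_formula("C4H8NO4")   # [M+H]+
  families <- list(
    new_family("134/88", "+", 134, 88, pos, list(component(2:4, "C3H6NO2", 1))),
    new_family("134/74", "+", 134, 74, pos, list(component(1:2, "C2H4NO2", 1))),
    new_family("134/43", "+", 134, 43, pos, list(component(frag_43, "C2H3O", 1))),
    new_family("132/88", "-", 132, 88, neg,
               list(component(1:3, "C3H6NO2", w88[1]),
                    component(2:4, "C3H6NO2", w88[2])))
  )
  new_molecule("aspartate", 4L, parse_formula("C4H7NO4"), families)
}

new_molecule <- function(name, n_carbons, neutral_formula, families) {
  if (formula_count(neutral_formula, "C") != n_carbons) {
    stop("n_carbons does not match the carbon count of the neutral formula")
  }
  for (fam in families) {
    for (cmp in fam$components) {
      if (any(cmp$carbons < 1L | cmp$carbons > n_carbons)) {
        stop("family ", fam$id, ": retained carbon index out of range")
      }
    }
  }
  structure(list(name = name, n_carbons = n_carbons,
                 neutral_formula = neutral_formula, families = families),
            class = "molecule_spec")
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat(sprintf("<molecule_spec> %s: %d carbons, %d isotopomers\n",
              x$name, x$n_carbons, 2L^x$n_carbons))
  for (fam in x$families) {
    cmp <- vapply(fam$components, function(cc)
      sprintf("C%d-%d (w=%.4g)", min(cc$carbons), max(cc$carbons), cc$weight),
      character(1))
    cat(sprintf("  %s [%s]  %s\n", fam$id, fam$polarity,
                paste(cmp, collapse = " + ")))
  }
  invisible(x)
}

#' Coerce a molecule name to its built-in \code{molecule_spec}
#'
#' @param molecule a \code{molecule_spec} (returned unchanged) or one of
#'   \code{"glutamate"}, \code{"aspartate"}.
#' @return a \code{molecule_spec}.
#' @examples
#' as_molecule("aspartate")$n_carbons  # 4
#' @export
as_molecule <- function(molecule) {
  if (inherits(molecule, "molecule_spec")) return(molecule)
  if (is.character(molecule) && length(molecule) == 1L) {
    return(switch(molecule,
                  glutamate = glutamate(),
                  aspartate = aspartate(),
                  stop("unknown molecule: ", molecule)))
  }
  stop("molecule must be a molecule_spec or one of \"glutamate\", \"aspartate\"")
}

#' Enumerate all binary 13C labelings of a molecule
#'
#' Returns the 2^n labelings of an n-carbon molecule in lexicographic order of
#' their bit strings (\code{"00..0"} first, \code{"11..1"} last). This order is
#' the canonical column order of every mapping matrix and fraction vector in
#' the package. Position k of a bit string is carbon Ck, C1 leftmost.
#'
#' @param molecule a \code{molecule_spec}, molecule name, or an integer carbon
#'   count.
#' @return 0/1 integer matrix with one row per labeling, columns C1..Cn,
#'   rownames the bit strings.
#' @examples
#' enumerate_labelings(2)
#' nrow(enumerate_labelings(glutamate()))  # 32
#' @export
enumerate_labelings <- function(molecule) {
  n <- if (is.numeric(molecule)) as.integer(molecule) else as_molecule(molecule)$n_carbons
  stopifnot(n >= 1L)
  # row r encodes r-1 in binary, C1 = most significant bit => lexicographic order
  idx <- 0:(2L^n - 1L)
  L <- matrix(0L, length(idx), n, dimnames = list(NULL, paste0("C", seq_len(n))))
  for (k in seq_len(n)) {
    L[, k] <- idx %/% 2L^(n - k) %% 2L
  }
  rownames(L) <- apply(L, 1, paste, collapse = "")
  L
}

#' Labeling strings in canonical order
#'
#' @inheritParams enumerate_labelings
#' @return character vector of bit strings, lexicographically ordered.
#' @export
labeling_strings <- function(molecule) rownames(enumerate_labelings(molecule))

as_bits <- function(labeling, n = NULL) {
  if (is.character(labeling)) {
    b <- as.integer(strsplit(labeling, "")[[1]])
  } else {
    b <- as.integer(labeling)
  }
  if (!all(b %in% c(0L, 1L))) stop("labeling must be binary")
  if (!is.null(n) && length(b) != n) stop("labeling has wrong length")
  b
}

#' Precursor and product mass shifts of a labeled fragment
#'
#' For a labeling and a fragment defined by its retained carbons, returns the
#' ion-pair mass shift \code{c(i, j)}: \code{i} is the total number of 13C in
#' the precursor, \code{j} the number falling inside the retained carbons
#' (always \code{j <= i}).
#'
#' @param labeling bit string (e.g. \code{"11000"}) or 0/1 vector.
#' @param carbons integer vector of retained carbon positions.
#' @return named integer vector \code{c(i = , j = )}.
#' @examples
#' fragment_shift("11000", 1:4)  # i = 2, j = 2
#' fragment_shift("11000", 2:5)  # i = 2, j = 1
#' @export
fragment_shift <- function(labeling, carbons) {
  b <- as_bits(labeling)
  if (any(carbons < 1L | carbons > length(b))) {
    stop("retained carbon index out of range")
  }
  c(i = sum(b), j = sum(b[carbons]))
}

#' Ion pairs produced by one labeling under a transition family
#'
#' Each fragment component of the family contributes its weight at the ion
#' pair implied by \code{\link{fragment_shift}}; components mapping to the same
#' (i, j) are summed. Weights always sum to 1.
#'
#' @param labeling bit string or 0/1 vector.
#' @param family a \code{transition_family} (an element of
#'   \code{molecule$families}).
#' @return data.frame with columns \code{i}, \code{j}, \code{q1}, \code{q3}
#'   (nominal m/z of the shifted ion pair), \code{id} and \code{weight}.
#' @examples
#' glu <- glutamate()
#' transition_signature("11000", glu$families[[3]])  # 148/104 : 148/103 = 0.95 : 0.05
#' @export
transition_signature <- function(labeling, family) {
  sh <- lapply(family$components, function(cmp) fragment_shift(labeling, cmp$carbons))
  i <- vapply(sh, `[[`, integer(1), "i")
  j <- vapply(sh, `[[`, integer(1), "j")
  w <- vapply(family$components, `[[`, numeric(1), "weight")
  key <- paste(i, j)
  agg <- rowsum(w, key)
  uk <- !duplicated(key)
  out <- data.frame(i = i[uk], j = j[uk],
                    q1 = family$q1 + i[uk], q3 = family$q3 + j[uk],
                    weight = agg[match(key[uk], rownames(agg)), 1],
                    row.names = NULL)
  out$id <- sprintf("%d/%d", out$q1, out$q3)
  out[order(out$i, out$j), c("i", "j", "q1", "q3", "id", "weight")]
}

#' Component weights of a mixed fragment from measured standard areas
#'
#' Converts the two peak areas of a resolved ion-pair doublet from a
#' positionally labeled standard (e.g. 148/104 vs 148/103 from a \code{11000}
#' glutamate standard) into the ratio and the component weights used for a
#' two-component mixed transition family.
#'
#' @param area_a,area_b nonnegative peak areas of the two component ion pairs.
#' @return list with \code{ratio} (a : b) and \code{weights}
#'   \code{c(a, b) / (a + b)}.
#' @examples
#' calibrate_mixture_ratio(19, 1)$weights  # 0.95 0.05
#' @export
calibrate_mixture_ratio <- function(area_a, area_b) {
  stopifnot(area_a >= 0, area_b >= 0)
  if (area_a + area_b == 0) stop("both areas are zero")
  list(ratio = area_a / area_b,
       weights = c(area_a, area_b) / (area_a + area_b))
}

#' Default transition tables as a data frame
#'
#' Flat CSV-exportable listing of the transition families of a molecule:
#' one row per fragment component with its family id, polarity, nominal Q1/Q3,
#' retained carbons, mixture weight and product-ion formula.
#'
#' @inheritParams enumerate_labelings
#' @return data.frame with columns \code{family_id}, \code{polarity},
#'   \code{Q1}, \code{Q3}, \code{fragment_carbons}, \code{weight},
#'   \code{product_formula}.
#' @export
transition_table <- function(molecule) {
  mol <- as_molecule(molecule)
  rows <- lapply(mol$families, function(fam) {
    do.call(rbind, lapply(fam$components, function(cmp) {
      data.frame(family_id = fam$id, polarity = fam$polarity,
                 Q1 = fam$q1, Q3 = fam$q3,
                 fragment_carbons = paste0("C", min(cmp$carbons), "-", max(cmp$carbons)),
                 weight = cmp$weight,
                 product_formula = paste0(names(cmp$product_formula),
                                          ifelse(cmp$product_formula > 1,
                                                 cmp$product_formula, ""),
                                          collapse = ""),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
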