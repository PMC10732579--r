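#' Condense oxaloacetate with acetyl-CoA into a glutamate labeling
#'
#' Carbon map of citrate synthase followed by oxidation to alpha-ketoglutarate
#' (tracked here as glutamate, its transamination partner): glutamate bits are
#' \code{(OAA C4, OAA C3, OAA C2, AcCoA C2, AcCoA C1)}; OAA C1 leaves as the
#' CO2 lost between citrate and alpha-ketoglutarate. Acetyl-CoA C1 is the
#' carbonyl carbon, C2 the methyl.
#'
#' @param oaa 4-carbon labeling (bit string or 0/1 vector).
#' @param accoa 2-carbon labeling.
#' @return glutamate labeling as a bit string.
#' @examples
#' condense_accoa("1110", "11")  # "01111"
#' condense_accoa("0000", "11")  # "00011"
#' @export
condense_accoa <- function(oaa, accoa) {
  o <- as_bits(oaa, 4L)
  a <- as_bits(accoa, 2L)
  paste(c(o[4], o[3], o[2], a[2], a[1]), collapse = "")
}

#' Return glutamate carbons to the oxaloacetate pool
#'
#' Alpha-ketoglutarate dehydrogenase removes C1; the remaining chain C2..C5
#' passes through symmetric succinate/fumarate into oxaloacetate either in
#' order (C2->C1 .. C5->C4) or reversed. With \code{scramble = TRUE} both
#' orientations are returned with weight 1/2 (fumarate hydratase active);
#' with \code{scramble = FALSE} only the in-order product is formed.
#'
#' @param glu 5-carbon glutamate labeling.
#' @param scramble logical: fumarate scrambling active?
#' @return named numeric vector of OAA labeling probabilities.
#' @examples
#' glutamate_to_oaa("00011")                    # 0011 and 1100, 1/2 each
#' glutamate_to_oaa("00011", scramble = FALSE)  # 0011 only
#' @export
glutamate_to_oaa <- function(glu, scramble = TRUE) {
  g <- as_bits(glu, 5L)
  fwd <- paste(g[2:5], collapse = "")
  if (!scramble) return(setNames(1, fwd))
  rev_ <- paste(rev(g[2:5]), collapse = "")
  if (fwd == rev_) return(setNames(1, fwd))
  setNames(c(0.5, 0.5), c(fwd, rev_))
}

#' TCA labeling scenario
#'
#' Bundles the inputs of the minimal TCA-turn simulator: the acetyl-CoA
#' labeling distribution, the pyruvate-carboxylase OAA inflow and its
#' fractional contribution, unlabeled anaplerotic dilution, fumarate
#' scrambling, and the number of turns. Distributions are given as named
#' vectors over bit strings and are normalized.
#'
#' @param accoa named distribution over 2-carbon acetyl-CoA labelings
#'   (\code{"00"}, \code{"10"}, \code{"01"}, \code{"11"}); C1 = carbonyl.
#' @param pc_oaa named distribution over 4-carbon OAA labelings entering by
#'   carboxylation.
#' @param pc_fraction fraction of the OAA inflow supplied by PC.
#' @param dilution unlabeled OAA inflow fraction per condensation.
#' @param scramble fumarate hydratase scrambling on/off.
#' @param n_turns number of TCA turns simulated.
#' @param purity tracer 13C isotopic purity; labeled positions of the inflow
#'   distributions are thinned per position to this probability before the
#'   run (1 = ideal tracer).
#' @return object of class \code{"tca_scenario"}.
#' @export
tca_scenario <- function(accoa = c("11" = 1), pc_oaa = c("1110" = 1),
                         pc_fraction = 0, dilution = 0, scramble = TRUE,
                         n_turns = 8L, purity = 1) {
  stopifnot(pc_fraction >= 0, pc_fraction <= 1, dilution >= 0, dilution < 1,
            n_turns >= 1, purity > 0, purity <= 1)
  structure(list(accoa = full_dist(accoa, 2L, purity),
                 pc_oaa = full_dist(pc_oaa, 4L, purity),
                 pc_fraction = pc_fraction, dilution = dilution,
                 scramble = scramble, n_turns = as.integer(n_turns)),
            class = "tca_scenario")
}

# expand a sparse named labeling distribution to the full canonical vector,
# optionally applying per-position Bernoulli thinning for tracer purity
full_dist <- function(x, n, purity = 1) {
  labs <- labeling_strings(n)
  out <- setNames(numeric(length(labs)), labs)
  if (any(!names(x) %in% labs)) stop("unknown labeling in distribution")
  out[names(x)] <- x
  if (any(out < 0) || sum(out) <= 0) stop("invalid distribution")
  out <- out / sum(out)
  if (purity < 1) {
    thinned <- setNames(numeric(length(labs)), labs)
    L <- enumerate_labelings(n)
    for (src in which(out > 0)) {
      bits <- L[src, ]
      k <- which(bits == 1L)
      # each labeled position independently retains its label w.p. purity
      for (tgt in seq_along(labs)) {
        tb <- L[tgt, ]
        if (any(tb > bits)) next
        p <- prod(ifelse(bits[k] == 1L,
                         ifelse(tb[k] == 1L, purity, 1 - purity), 1))
        thinned[tgt] <- thinned[tgt] + out[src] * p
      }
    }
    out <- thinned
  }
  out
}

#' Run the minimal TCA labeling simulator
#'
#' Propagates full labeling distributions (no Monte Carlo) through repeated
#' TCA turns: the OAA pool is mixed with the PC inflow and unlabeled
#' anaplerotic dilution, condensed with the acetyl-CoA distribution into
#' glutamate, and regenerated through the (optionally scrambling)
#' succinate/fumarate segment. The aspartate distribution mirrors the mixed
#' OAA pool that condenses (transamination preserves the carbon skeleton);
#' with scrambling on, that pool is first equilibrated through symmetric
#' fumarate, which equalizes mirror-image labelings (1110 with 0111, and so
#' on). Both outputs are normalized every turn; the run is fully
#' deterministic.
#'
#' @param scenario a \code{\link{tca_scenario}}.
#' @return list with \code{glutamate} (32 fractions) and \code{aspartate}
#'   (16 fractions), both in canonical labeling order.
#' @examples
#' sim <- run_tca(tca_scenario(accoa = c("11" = 1), n_turns = 1))
#' sim$glutamate["00011"]  # first turn puts all mass at glutamate 00011
#' @export
run_tca <- function(scenario) {
  stopifnot(inherits(scenario, "tca_scenario"))
  labs4 <- labeling_strings(4L)
  labs5 <- labeling_strings(5L)
  labs2 <- labeling_strings(2L)
  oaa <- setNames(numeric(16), labs4)
  oaa[["0000"]] <- 1
  glu <- setNames(numeric(32), labs5)
  # precompute condensation and mirror-image index maps
  cond_idx <- outer(labs4, labs2, Vectorize(function(o, a) condense_accoa(o, a)))
  mirror <- vapply(strsplit(labs4, ""), function(s) paste(rev(s), collapse = ""),
                   character(1))
  asp <- oaa
  for (turn in seq_len(scenario$n_turns)) {
    oin <- (1 - scenario$pc_fraction) * oaa + scenario$pc_fraction * scenario$pc_oaa
    oin <- (1 - scenario$dilution) * oin
    oin[["0000"]] <- oin[["0000"]] + scenario$dilution
    if (scenario$scramble) {
      # fumarate back-exchange equilibrates the pool with its mirror image
      oin <- (oin + setNames(oin[mirror], labs4)) / 2
    }
    asp <- oin
    glu[] <- 0
    for (oi in seq_along(labs4)) {
      if (oin[oi] == 0) next
      for (ai in seq_along(labs2)) {
        w <- oin[oi] * scenario$accoa[ai]
        if (w == 0) next
        glu[[cond_idx[oi, ai]]] <- glu[[cond_idx[oi, ai]]] + w
      }
    }
    glu <- glu / sum(glu)
    oaa[] <- 0
    for (gi in seq_along(labs5)) {
      if (glu[gi] == 0) next
      tr <- glutamate_to_oaa(labs5[gi], scenario$scramble)
      for (nm in names(tr)) oaa[[nm]] <- oaa[[nm]] + glu[gi] * tr[[nm]]
    }
    oaa <- oaa / sum(oaa)
  }
  list(glutamate = glu, aspartate = asp)
}

#' Measurement noise model for simulated MRM tables
#'
#' Multiplicative log-normal noise with a given relative standard deviation
#' plus an additive area floor.
#'
#' @param rsd relative standard deviation of the multiplicative noise.
#' @param floor additive area floor (arbitrary units).
#' @return object of class \code{"noise_model"}.
#' @export
noise_model <- function(rsd = 0.05, floor = 0) {
  stopifnot(rsd >= 0, floor >= 0)
  structure(list(rsd = rsd, floor = floor), class = "noise_model")
}

#' Forward-model an isotopomer distribution into an MRM intensity table
#'
#' Computes the per-family transition intensity fractions predicted by the
#' mapping matrix, scales each family to \code{total_area}, and optionally
#' applies measurement noise. The output schema matches
#' \code{\link{read_intensity_csv}}, so simulated tables run through the same
#' pipeline as measured ones.
#'
#' @param dist fraction vector in canonical labeling order.
#' @param A a \code{\link{mapping_matrix}} for the same molecule.
#' @param noise a \code{\link{noise_model}} or \code{NULL} (noiseless).
#' @param total_area per-family total area.
#' @param sample_id sample identifier written into the table.
#' @return data.frame with columns \code{sample_id}, \code{Q1}, \code{Q3},
#'   \code{area}.
#' @export
simulate_mrm <- function(dist, A, noise = NULL, total_area = 1e6,
                         sample_id = "sim1") {
  if (total_area <= 0) stop("total_area must be positive")
  dist <- as_distribution(dist)
  stopifnot(length(dist) == ncol(A))
  frac <- as.numeric(unclass(A) %*% dist)
  tr <- attr(A, "transitions")
  area <- frac * total_area
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    if (noise$rsd > 0) {
      sdlog <- sqrt(log1p(noise$rsd^2))
      area <- area * stats::rlnorm(length(area), -sdlog^2 / 2, sdlog)
    }
    area <- area + noise$floor
  }
  data.frame(sample_id = sample_id, Q1 = tr$q1, Q3 = tr$q3, area = area,
             stringsAsFactors = FALSE)
}
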