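# shared fixtures: matrices are expensive enough to build once per run
glu <- glutamate()
asp <- aspartate()
A_glu <- mapping_matrix(glu)
A_asp <- mapping_matrix(asp)
A_glu_na <- mapping_matrix(glu, na_correct = TRUE)
A_asp_na <- mapping_matrix(asp, na_correct = TRUE)

glu_labs <- labeling_strings(glu)
asp_labs <- labeling_strings(asp)

# sparse named fractions -> full canonical vector
dist_of <- function(..., n = 5L) {
  x <- c(...)
  out <- setNames(numeric(2^n), labeling_strings(n))
  out[names(x)] <- x
  out / sum(out)
}

# noiseless per-family intensity fractions for a ground-truth vector
forward_b <- function(x, A) {
  normalize_intensities(as.numeric(unclass(A) %*% x), A)
}
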