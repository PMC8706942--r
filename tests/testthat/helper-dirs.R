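# Align a texture_matrix object's per-direction matrices with the 13-slot
# direction list used by the oracles (builders drop empty directions).
expand_dirs <- function(m) {
  offs <- oracle_offsets13()
  out <- vector("list", nrow(offs))
  for (i in seq_along(m$matrices)) {
    hit <- which(apply(offs, 1, function(o) all(o == m$directions[[i]])))
    stopifnot(length(hit) == 1)
    out[[hit]] <- m$matrices[[i]]
  }
  out
}
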