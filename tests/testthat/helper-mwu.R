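# Construct a pair of tie-free samples of sizes (nx, ny) realizing a given
# Mann-Whitney U for the first sample, by placing the x's among the y's in
# sorted order.
mwu_samples_for_u <- function(nx, ny, u) {
  stopifnot(u >= 0, u <= nx * ny)
  k <- u %/% ny   # x's above all y's
  r <- u %% ny    # y's below the one middle x
  if (k == nx) {
    labs <- c(rep("y", ny), rep("x", nx))
  } else {
    labs <- c(rep("x", nx - k - 1), rep("y", r), "x",
              rep("y", ny - r), rep("x", k))
  }
  vals <- seq_along(labs)  # strictly increasing, no ties
  list(x = vals[labs == "x"], y = vals[labs == "y"])
}
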