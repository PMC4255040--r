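# Shared histogram construction. `values` are binned on [0 or lo, hi) with
# fixed-width bins; "unit_area" scales heights so the histogram integrates to
# one; "per_contributing_atom" divides raw counts by (n_contributing * bin
# width) so a delta fixture has height 1/bin_width when every atom contributes.
new_histogram <- function(values, bin_width, hi, lo = 0,
                          normalization = c("unit_area", "per_contributing_atom"),
                          n_contributing = length(values), extra = list()) {
  normalization <- match.arg(normalization)
  nb <- max(1L, ceiling((hi - lo) / bin_width - 1e-9))
  edges <- lo + bin_width * (0:nb)
  counts <- if (length(values) == 0) {
    rep(0, length(edges) - 1)
  } else {
    idx <- findInterval(values, edges, rightmost.closed = TRUE, left.open = FALSE)
    idx <- idx[idx >= 1 & idx <= length(edges) - 1]
    tabulate(idx, nbins = length(edges) - 1)
  }
  dens <- if (normalization == "unit_area") {
    tot <- sum(counts) * bin_width
    if (tot > 0) counts / tot else counts * 0
  } else {
    if (n_contributing > 0) counts / (n_contributing * bin_width) else counts * 0
  }
  out <- tibble(
    bin_left = edges[-length(edges)],
    bin_center = edges[-length(edges)] + bin_width / 2,
    bin_right = edges[-1],
    density = dens,
    count = counts
  )
  attr(out, "normalization") <- normalization
  attr(out, "n_contributing") <- n_contributing
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("md_histogram", class(out))
  out
}

#' @export
print.md_histogram <- function(x, ...) {
  cat(sprintf("<md_histogram> %d bins, normalization = %s\n",
              nrow(x), attr(x, "normalization")))
  NextMethod()
}
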