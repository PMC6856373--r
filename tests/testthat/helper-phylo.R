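# Support of the bipartition separating `tips` from the rest, looked up on
# the unrooted bootstrapped tree (avoids node-label shuffling on reroot).
bipart_support <- function(tr, tips) {
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  target <- sort(match(tips, labs))
  comp <- sort(setdiff(seq_along(labs), target))
  sup <- attr(tr, "support")
  for (k in seq_along(pp)) {
    s <- sort(pp[[k]])
    if (identical(s, target) || identical(s, comp)) return(sup[k])
  }
  NA_real_
}
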