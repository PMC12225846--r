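# shared small fixtures, built once per test run

fixturePairs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(1:12, function(s) makeGlottisPair(seed = s))
    }
    cache
  }
})

# brute-force IoU by explicit pixel counting (independent of iou())
bruteIoU <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (p in seq_along(a)) {
    af <- a[p] > 0.5; bf <- b[p] > 0.5
    if (af && bf) inter <- inter + 1L
    if (af || bf) uni <- uni + 1L
  }
  if (uni == 0L) 1 else inter / uni
}

# solid square mask helper
squareMask <- function(side, rs, cs) {
  m <- matrix(0, side, side)
  m[rs, cs] <- 1
  m
}
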