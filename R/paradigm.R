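#' Construct a gas paradigm
#'
#' @param totalDuration total scan duration, seconds
#' @param hcBlocks two-column matrix (onset, duration) of hypercapnia blocks
#' @param hoBlocks two-column matrix (onset, duration) of hyperoxia blocks
#' @return a validated [GasParadigm-class] object
#' @export
gasParadigm <- function(totalDuration, hcBlocks, hoBlocks) {
  new("GasParadigm", totalDuration = as.numeric(totalDuration),
      hcBlocks = matrix(as.numeric(hcBlocks), ncol = 2,
                        dimnames = list(NULL, c("onset", "duration"))),
      hoBlocks = matrix(as.numeric(hoBlocks), ncol = 2,
                        dimnames = list(NULL, c("onset", "duration"))))
}

#' Default 18-minute interleaved hypercapnia/hyperoxia paradigm
#'
#' The Bulte-style gas schedule used for generalized-calibration experiments:
#' 18 minutes total, alternating two 2-min hypercapnia (HC) blocks and two
#' 3-min hyperoxia (HO) blocks. Each HC block is followed by 1 min of
#' normocapnia before the HO block starts, and each HO block by 3 min of
#' normoxia.
#'
#' Timeline (minutes): 2 baseline | 2 HC | 1 rest | 3 HO | 3 rest |
#' 2 HC | 1 rest | 3 HO | 1 rest.
#'
#' @return a [GasParadigm-class] of total duration 1080 s
#' @export
#' @examples
#' p <- makeDefaultParadigm()
#' totalDuration(p)  # 1080
makeDefaultParadigm <- function() {
  gasParadigm(
    totalDuration = 1080,
    hcBlocks = rbind(c(120, 120), c(660, 120)),
    hoBlocks = rbind(c(300, 180), c(840, 180)))
}

## Block indicator for one condition sampled on a time grid.
blockIndicator <- function(blocks, times) {
  out <- numeric(length(times))
  for (i in seq_len(nrow(blocks)))
    out <- out + as.numeric(times >= blocks[i, 1] &
                            times < blocks[i, 1] + blocks[i, 2])
  pmin(out, 1)
}
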