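#' Electrode grid layout of the 32-channel forearm sleeve
#'
#' The recording sleeve carries two 16-channel faces: one over the wrist
#' flexor musculature and one over the extensors.  Each face is a 4 x 4
#' grid.  The flexor face holds channels 5-8, 13-16, 21-24 and 29-32 (one
#' row per group of four); the extensor face holds channels 1-4, 9-12,
#' 17-20 and 25-28.  Columns run left to right in increasing channel
#' number within each row.
#'
#' @return A data frame with one row per channel and columns `channel`
#'   (1-32), `side` (`"flexor"` or `"extensor"`), `row` and `col` (1-4).
#' @examples
#' lay <- channel_layout()
#' subset(lay, channel == 5)   # flexor, row 1, col 1
#' @export
channel_layout <- function() {
  flexor <- rbind(5:8, 13:16, 21:24, 29:32)
  extensor <- rbind(1:4, 9:12, 17:20, 25:28)
  build <- function(m, side) {
    data.frame(channel = as.vector(t(m)),
               side = side,
               row = rep(1:4, each = 4),
               col = rep(1:4, times = 4))
  }
  out <- rbind(build(flexor, "flexor"), build(extensor, "extensor"))
  out <- out[order(out$channel), ]
  rownames(out) <- NULL
  out
}

#' 4 x 4 channel-number matrix for one face of the sleeve
#'
#' @param side `"flexor"` or `"extensor"`.
#' @param layout A layout data frame from [channel_layout()].
#' @return Integer 4 x 4 matrix of channel ids, rows/cols as worn.
#' @export
layout_grid <- function(side = c("flexor", "extensor"), layout = channel_layout()) {
  side <- match.arg(side)
  sub <- layout[layout$side == side, ]
  m <- matrix(NA_integer_, 4, 4)
  m[cbind(sub$row, sub$col)] <- sub$channel
  m
}

## Channel source map for a rigid rotation of the sleeve by `shift` grid
## columns: the electrode now sitting at (side, row, col) picks up the
## signal formerly seen at (side, row, col - shift), wrapping around the
## arm.  Returns src such that new[, ch] = old[, src[ch]].
shift_permutation <- function(shift, layout = channel_layout()) {
  stopifnot(abs(shift) < 4)
  src <- integer(32)
  for (i in seq_len(nrow(layout))) {
    ch <- layout$channel[i]
    src_col <- ((layout$col[i] - shift - 1) %% 4) + 1
    j <- layout$side == layout$side[i] & layout$row == layout$row[i] &
      layout$col == src_col
    src[ch] <- layout$channel[j]
  }
  src
}
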