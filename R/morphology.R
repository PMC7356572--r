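# Binary morphology on small masks. Square structuring elements only.
# Border convention: out-of-image pixels count as background for dilation
# and as foreground for erosion, so closing is extensive (never removes
# original foreground) and idempotent, matching the usual image-processing
# toolbox behavior.

shift_pad <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

binary_dilate <- function(mask, selem_size = 3L) {
  h <- (selem_size - 1L) %/% 2L
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dr in -h:h) for (dc in -h:h)
    out <- out | shift_pad(mask, dr, dc, FALSE)
  out
}

binary_erode <- function(mask, selem_size = 3L) {
  h <- (selem_size - 1L) %/% 2L
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (dr in -h:h) for (dc in -h:h)
    out <- out & shift_pad(mask, dr, dc, TRUE)
  out
}

binary_close <- function(mask, selem_size = 3L) {
  binary_erode(binary_dilate(mask, selem_size), selem_size)
}

# 8-connectivity connected-component labeling via iterative label
# propagation (grids here are at most a few thousand pixels).
label_components <- function(mask) {
  lbl <- matrix(0L, nrow(mask), ncol(mask))
  lbl[mask] <- seq_len(sum(mask))
  repeat {
    nb <- lbl
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      s <- shift_pad(lbl, dr, dc, 0L)
      upd <- mask & s > 0L & (nb == 0L | s < nb)
      nb[upd] <- s[upd]
    }
    if (all(nb == lbl)) break
    lbl <- nb
  }
  # compact label ids
  ids <- sort(unique(lbl[lbl > 0L]))
  if (length(ids)) lbl[lbl > 0L] <- match(lbl[lbl > 0L], ids)
  lbl
}

remove_small_components <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lbl <- label_components(mask)
  sizes <- tabulate(lbl[lbl > 0L])
  keep <- which(sizes >= min_px)
  lbl %in% keep & mask
}
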