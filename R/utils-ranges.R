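# Inclusive integer range helpers. Ranges are 2-column matrices
# (start, end), author-numbered, 1-based, inclusive at both ends.

.asRangeMatrix <- function(r) {
  if (is.null(r))
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  if (is.numeric(r) && is.null(dim(r))) {
    if (length(r) == 2L) r <- matrix(r, ncol = 2, byrow = TRUE)
    else stop("a range must be c(start, end); give several as a list")
  }
  if (is.list(r) && !is.data.frame(r))
    r <- do.call(rbind, lapply(r, function(z) {
      if (length(z) == 1L) z <- c(z, z)
      if (length(z) != 2L) stop("each range must be c(start, end)")
      z
    }))
  r <- matrix(as.integer(r), ncol = 2)
  if (nrow(r) > 0 && any(r[, 1] > r[, 2]))
    stop("range start must be <= end")
  colnames(r) <- c("start", "end")
  r
}

.inRanges <- function(x, ranges) {
  if (nrow(ranges) == 0) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  for (i in seq_len(nrow(ranges)))
    hit <- hit | (x >= ranges[i, 1] & x <= ranges[i, 2])
  hit
}

# collapse a sorted integer vector into maximal runs -> range matrix
.runsToRanges <- function(v) {
  if (length(v) == 0)
    return(.asRangeMatrix(NULL))
  v <- sort(unique(as.integer(v)))
  brk <- which(diff(v) > 1L)
  start <- v[c(1L, brk + 1L)]
  end <- v[c(brk, length(v))]
  m <- cbind(start = start, end = end)
  storage.mode(m) <- "integer"
  m
}
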