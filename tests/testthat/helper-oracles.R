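# Independent oracles and small fixture builders used across the suite.

# naive double-loop mean pairwise distance (the oracle stays loop-based
# on purpose; the implementation uses stats::dist)
mpd_oracle <- function(pts) {
  n <- nrow(pts)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sqrt(sum((pts[i, ] - pts[j, ])^2))
  tot / (n * (n - 1) / 2)
}

# two-sided Mann-Whitney p-value by complete enumeration of all
# C(n_a + n_b, n_a) group labelings (no ties assumed)
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx)
    sum(r[idx]) - na * (na + 1) / 2)
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}

# a disk of the given radius stamped onto a matrix, returning a Field
# with one channel plus its binary ground truth
disk_field <- function(centers, radius = 12, size = c(100, 100),
                       fg = 200, bg = 5) {
  img <- matrix(bg, size[1], size[2])
  truth <- matrix(0L, size[1], size[2])
  rows <- row(img); cols <- col(img)
  for (i in seq_len(nrow(centers))) {
    inside <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <= radius^2
    img[inside] <- fg
    truth[inside] <- i
  }
  list(field = new_field(list(ch = img)), truth = truth)
}

# CellRegion for a filled axis-aligned rectangle of pixels
rect_region <- function(r0, r1, c0, c1, size = NULL) {
  px <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
  mask_dim <- if (is.null(size)) c(r1 + 2, c1 + 2) else size
  mask <- matrix(0L, mask_dim[1], mask_dim[2])
  mask[px] <- 1L
  extract_regions(mask)[[1]]
}

# greedy IoU matching of detected labels against a ground-truth mask;
# returns per-truth-cell IoU (0 when undetected)
match_iou <- function(truth, detected) {
  vapply(seq_len(max(truth)), function(k) {
    tk <- truth == k
    hits <- detected[tk]
    hits <- hits[hits > 0]
    if (!length(hits)) return(0)
    lab <- as.integer(names(which.max(table(hits))))
    dk <- detected == lab
    sum(tk & dk) / sum(tk | dk)
  }, numeric(1))
}

two_channel_specs <- function(kappa_ref = 8, kappa_marker = 8,
                              marker_offset = 0) {
  list(cd44 = membrane_channel(kappa = kappa_ref),
       marker = membrane_channel(kappa = kappa_marker,
                                 cap_offset = marker_offset))
}
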