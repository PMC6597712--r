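# match detected events to injected ground truth within a spatiotemporal
# tolerance; returns counts of true positives and false positives
match_events <- function(detected, truth, dt = 2, dpx = 3) {
  de <- events(detected)
  tp <- sum(vapply(seq_len(nrow(truth)), function(i) {
    any(abs(de$frame - truth$frame[i]) <= dt &
        sqrt((de$row - truth$row[i])^2 + (de$col - truth$col[i])^2) <= dpx)
  }, logical(1)))
  fp <- nrow(de) - sum(vapply(seq_len(nrow(de)), function(j) {
    any(abs(de$frame[j] - truth$frame) <= dt &
        sqrt((de$row[j] - truth$row)^2 + (de$col[j] - truth$col)^2) <= dpx)
  }, logical(1)))
  list(tp = tp, fp = fp)
}

# disk mask fixture on a square image (0-based center coordinates)
disk_mask <- function(n, radius, center = (n - 1) / 2) {
  rr <- matrix(seq_len(n) - 1, n, n)
  cc <- t(rr)
  (rr - center)^2 + (cc - center)^2 <= radius^2
}
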