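# shared fixtures and small utilities

tm_sequence <- function() "TIIGVSVLSVLVVSVVAVLVY"   # TLR4 TM 632-652

f1_score <- function(found, truth) {
  tp <- length(intersect(found, truth))
  if (tp == 0) return(0)
  precision <- tp / length(found)
  recall <- tp / length(truth)
  2 * precision * recall / (precision + recall)
}

# angle between two unit vectors, radians
vec_angle <- function(a, b) {
  acos(pmin(1, pmax(-1, abs(sum(a * b)))))
}
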