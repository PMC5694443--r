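# Independent oracle for onset detection: test every observed day against
# the persistence rule with explicit index arithmetic.
oracle_onset <- function(days, values, threshold) {
  keep <- !is.na(values)
  days <- days[keep]; values <- values[keep]
  o <- order(days); days <- days[o]; values <- values[o]
  for (i in seq_along(days)) {
    if (values[i] > threshold) {
      if (i == length(days)) return(days[i])
      has_next <- any(days == days[i] + 1)
      if (has_next && values[days == days[i] + 1] > threshold) return(days[i])
    }
  }
  NA_integer_
}

# Printed per-method severity means of the nine repurposed compounds and
# the rank annotations they carry, one column per assessment method.
ranked_compounds <- tibble::tribble(
  ~compound, ~histo_total, ~dai, ~inflammation, ~score, ~joint,
  "MC-105",  6.3,  7.4, 3.02, 4.0, 0.08,
  "MC-103",  7.9,  7.9, 3.67, 5.3, 0.11,
  "MC-110",  8.2,  8.3, 3.81, 5.8, 0.11,
  "MC-114",  8.4,  8.3, 3.60, 4.3, 0.08,
  "MC-104",  8.9,  8.4, 4.06, 5.8, 0.11,
  "MC-106",  9.3,  9.4, 4.25, 5.8, 0.11,
  "MC-101",  9.8,  9.0, 4.27, 6.3, 0.12,
  "MC-112", 10.0,  9.5, 4.50, 6.4, 0.12,
  "MC-111", 10.3,  7.9, 4.38, 6.1, 0.11)
printed_ranks <- list(
  histo_total  = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
  dai          = c(1, 2, 4, 4, 6, 8, 7, 9, 2),
  inflammation = c(1, 3, 4, 2, 5, 6, 7, 9, 8),
  score        = c(1, 3, 4, 2, 4, 4, 8, 9, 7),
  joint        = c(1, 3, 3, 1, 3, 3, 8, 8, 3))
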