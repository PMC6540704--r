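# independent per-locus oracles, set-based / integer-dosage based
oracle_presence_sim <- function(clsA, clsB, index = "jaccard") {
  sets <- list(`1` = "X", `2` = c("X", "Y"), `3` = c("X", "Y"),
               `4` = c("X", "Y"), `5` = "Y")
  vals <- c()
  for (l in seq_along(clsA)) {
    if (is.na(clsA[l]) || is.na(clsB[l])) next
    A <- sets[[clsA[l]]]; B <- sets[[clsB[l]]]
    vals <- c(vals, if (index == "jaccard") {
      length(intersect(A, B)) / length(union(A, B))
    } else {
      2 * length(intersect(A, B)) / (length(A) + length(B))
    })
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

oracle_dosage_sim <- function(dA, dB, p) {
  # 1.5 codes averaged over their two compatible integer dosages
  expand <- function(d) if (d == 1.5) c(1, 2) else d
  vals <- c()
  for (l in seq_along(dA)) {
    if (is.na(dA[l]) || is.na(dB[l])) next
    combos <- expand.grid(a = expand(dA[l]), b = expand(dB[l]))
    share <- mean(apply(combos, 1, function(x) {
      (min(x[1], x[2]) + min(p - x[1], p - x[2])) / p
    }))
    vals <- c(vals, share)
  }
  if (!length(vals)) NA_real_ else mean(vals)
}
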