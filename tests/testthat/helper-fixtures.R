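# Shared fixtures: all built in code at test time.

toy_matrix <- function() {
  pa_matrix(rbind(A = c(1, 1, 0, 0),
                  B = c(0, 0, 1, 1),
                  C = c(1, 0, 1, 0)))
}

# Random binary matrix guaranteed to have no empty row or column (empty
# rows/columns get one occurrence planted at a random position).
random_pa <- function(R, C, p = 0.3) {
  ent <- matrix(rbinom(R * C, 1, p), R, C)
  for (i in which(rowSums(ent) == 0)) ent[i, sample.int(C, 1)] <- 1L
  for (j in which(colSums(ent) == 0)) ent[sample.int(R, 1), j] <- 1L
  pa_matrix(ent)
}

# Independent oracle: C-score by explicit double loop over species pairs.
naive_c_score <- function(m) {
  R <- nrow(m)
  total <- 0
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      S <- sum(m[i, ] == 1 & m[j, ] == 1)
      total <- total + (sum(m[i, ]) - S) * (sum(m[j, ]) - S)
    }
  }
  total / (R * (R - 1) / 2)
}

# Total-variation distance between sampled matrix keys and the uniform
# distribution over enumerated matrices.
tv_from_uniform <- function(keys, enum_keys) {
  K <- length(enum_keys)
  counts <- table(factor(keys, levels = enum_keys))
  sum(abs(as.numeric(counts) / length(keys) - 1 / K)) / 2
}

matrix_key <- function(m) paste(as.integer(t(m)), collapse = "")
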