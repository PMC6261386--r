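# Internal helpers shared across modules.

# Column-wise softmax of a logit matrix (V x n): each column is turned into a
# probability vector. Centering by the column max keeps exp() in range.
softmax_cols <- function(logits) {
  shifted <- sweep(logits, 2L, apply(logits, 2L, max), "-")
  e <- exp(shifted)
  sweep(e, 2L, colSums(e), "/")
}

# Deterministic sub-streams: one user-facing seed drives several independent
# draws (population, messages, outcomes, likes) without coupling them.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483399) + 1L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Extract the score matrix (users x k) and user ids from a score tibble
# (user_id, f1..fk) or a bare matrix.
score_matrix <- function(scores) {
  if (is.matrix(scores)) {
    return(list(users = rownames(scores) %||% as.character(seq_len(nrow(scores))),
                F = scores))
  }
  stopifnot(is.data.frame(scores))
  fac_cols <- setdiff(names(scores), "user_id")
  F <- as.matrix(scores[fac_cols])
  users <- if ("user_id" %in% names(scores)) as.character(scores$user_id)
           else as.character(seq_len(nrow(scores)))
  list(users = users, F = F)
}

scores_tibble <- function(users, F) {
  F <- as.matrix(F)
  colnames(F) <- paste0("f", seq_len(ncol(F)))
  dplyr::bind_cols(tibble::tibble(user_id = users), tibble::as_tibble(F))
}
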