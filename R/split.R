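# Identity-aware data splitting and per-loop structure sampling.

#' Aligned sequence identity of two sequences
#'
#' Global (Needleman-Wunsch) alignment with match +1, mismatch 0 and linear
#' gap penalty -1, followed by identity = matches / aligned columns x 100.
#' Ties in the dynamic program are broken deterministically (diagonal, then
#' up, then left) and the pair is ordered canonically before aligning, so
#' the function is symmetric.
#'
#' @param a,b Non-empty amino-acid sequences (character scalars).
#' @param match,mismatch,gap Scoring scheme (defaults +1 / 0 / -1).
#' @return Percent identity in \[0, 100\].
#' @export
aligned_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (b < a) { tmp <- a; a <- b; b <- tmp }   # canonical order => symmetry
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(A[i] == B, match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  # traceback, diagonal preferred
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + (if (A[i] == B[j]) match else mismatch)) {
      matches <- matches + (A[i] == B[j])
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    cols <- cols + 1L
  }
  100 * matches / cols
}

#' Identity-aware train/validation/test split of loop groups
#'
#' Groups are first merged into connected components under the relation
#' "aligned identity above `max_identity`" (restricted to equal loop length
#' when `length_matched_only`), so that no two groups exceeding the identity
#' cap can land in different splits. Components are then assigned whole,
#' largest first (ties shuffled under `seed`), each to the split with the
#' largest remaining deficit relative to the target fractions.
#'
#' @param groups List of `LoopGroup`s.
#' @param fractions Named fractions for `train`, `val`, `test`
#'   (default 0.70 / 0.15 / 0.15); must sum to 1.
#' @param max_identity Identity cap in percent (default 80).
#' @param length_matched_only Apply the cap only between groups of equal
#'   loop length (default TRUE, the split rule used for mined PDB loops).
#' @param seed RNG seed for tie shuffling.
#' @return Object of class `SplitAssignment`: data.frame with `group_key`,
#'   `split`; attributes `fractions`, `max_identity`, `seed`.
#' @export
make_splits <- function(groups, fractions = c(train = 0.70, val = 0.15,
                                              test = 0.15),
                        max_identity = 80, length_matched_only = TRUE,
                        seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (!all(c("train", "val", "test") %in% names(fractions))) {
    stop("fractions must be named train, val, test")
  }
  n <- length(groups)
  keys <- vapply(groups, `[[`, "", "group_key")
  seqs <- vapply(groups, function(g) g$members[[1]]$sequence, "")
  lens <- vapply(groups, function(g) g$members[[1]]$loop_length, 1L)

  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (length_matched_only && lens[i] != lens[j]) next
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      if (aligned_identity(seqs[i], seqs[j]) > max_identity) {
        parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  comp_ids <- unique(comp)
  comp_members <- lapply(comp_ids, function(cid) which(comp == cid))
  sizes <- lengths(comp_members)

  set.seed(seed)
  ord <- order(-sizes, stats::runif(length(sizes)))
  assigned <- stats::setNames(numeric(3), c("train", "val", "test"))
  split_of <- character(n)
  targets <- fractions[c("train", "val", "test")] * n
  for (k in ord) {
    members <- comp_members[[k]]
    if (length(members) > max(targets)) {
      warning("a connected component of ", length(members),
              " groups exceeds every split target; assigning to train")
      pick <- "train"
    } else {
      deficit <- targets - assigned
      pick <- c("train", "val", "test")[which.max(deficit)]
    }
    split_of[members] <- pick
    assigned[pick] <- assigned[pick] + length(members)
  }
  out <- data.frame(group_key = keys, split = split_of,
                    stringsAsFactors = FALSE)
  attr(out, "fractions") <- fractions
  attr(out, "max_identity") <- max_identity
  attr(out, "seed") <- seed
  class(out) <- c("SplitAssignment", "data.frame")
  out
}

#' Remove groups too similar to an external holdout set
#'
#' Supports holding out e.g. antibody/TCR CDR3 sequences: every group whose
#' loop sequence exceeds `max_identity` aligned identity to any holdout
#' sequence (regardless of length) is removed.
#'
#' @param groups List of `LoopGroup`s.
#' @param holdout_sequences Character vector of sequences to protect.
#' @param max_identity Identity cap in percent (default 80).
#' @return The retained subset of `groups`.
#' @export
remove_by_identity <- function(groups, holdout_sequences, max_identity = 80) {
  if (length(holdout_sequences) == 0L) return(groups)
  keep <- vapply(groups, function(g) {
    s <- g$members[[1]]$sequence
    all(vapply(holdout_sequences,
               function(h) aligned_identity(s, h) <= max_identity, TRUE))
  }, TRUE)
  groups[keep]
}

#' Sample structures of a loop group for training or validation
#'
#' Training uses several structures per loop (default 5) to stabilise
#' predictions against small coordinate changes; validation uses one.
#' Sampling is without replacement, capped at the group size, and seeded.
#'
#' @param group A `LoopGroup`.
#' @param k Number of structures to draw (default 5).
#' @param seed RNG seed.
#' @return List of `LoopMotif`s.
#' @export
sample_training_structures <- function(group, k = 5L, seed = 1L) {
  stopifnot(k >= 1L)
  n <- length(group$members)
  set.seed(seed)
  idx <- sample.int(n, size = min(k, n))
  group$members[idx]
}
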