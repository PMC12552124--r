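make_ann <- function(ss, partners_idx, chain = "A") {
  n <- length(ss)
  rt <- data.frame(chain = chain, resno = seq_len(n), insert = "",
                   stringsAsFactors = FALSE)
  rt$key <- loopflex:::res_key(rt$chain, rt$resno, rt$insert)
  partners <- lapply(seq_len(n), function(i) {
    rt$key[partners_idx[[i]]]
  })
  loopflex:::ss_annotation(rt, ss, partners)
}

test_that("a hairpin yields exactly one bridged strand pair", {
  fix <- generate_hairpin(4, strand_length = 4, seed = 1)
  pairs <- find_hairpin_pairs(fix$ss, "A")
  expect_length(pairs, 1L)
  expect_equal(pairs[[1]]$n_strand, fix$ss$key[1:4])
  expect_equal(pairs[[1]]$c_strand, fix$ss$key[9:12])
  expect_gte(pairs[[1]]$evidence, 1L)
})

test_that("an all-helix chain yields no strand pairs", {
  ann <- assign_secondary_structure(generate_ideal_helix(12))
  expect_length(find_hairpin_pairs(ann, "A"), 0L)
})

test_that("three strands bridged A-B and B-C give exactly two pairs", {
  # strands at 1-3, 7-9, 13-15 with antiparallel bridges between neighbours
  ss <- rep("other", 15)
  ss[c(1:3, 7:9, 13:15)] <- "strand"
  partners <- vector("list", 15)
  partners[[2]] <- 8L; partners[[8]] <- c(2L, 14L); partners[[14]] <- 8L
  ann <- make_ann(ss, partners)
  pairs <- find_hairpin_pairs(ann, "A")
  expect_length(pairs, 2L)
  expect_equal(pairs[[1]]$n_strand, ann$key[1:3])
  expect_equal(pairs[[1]]$c_strand, ann$key[7:9])
  expect_equal(pairs[[2]]$n_strand, ann$key[7:9])
  expect_equal(pairs[[2]]$c_strand, ann$key[13:15])
})

test_that("consecutive strands without a mutual bridge are not paired", {
  ss <- rep("other", 10)
  ss[c(1:3, 8:10)] <- "strand"
  ann <- make_ann(ss, vector("list", 10))
  expect_length(find_hairpin_pairs(ann, "A"), 0L)
})

test_that("extract_loop_motif takes exactly the residues between strands", {
  fix <- generate_hairpin(6, seed = 4)
  pair <- find_hairpin_pairs(fix$ss, "A")[[1]]
  m <- extract_loop_motif(fix$structure, pair)
  expect_s3_class(m, "LoopMotif")
  expect_equal(m$loop_length, 6L)
  expect_equal(m$residues$key, fix$loop_keys)
  expect_equal(nchar(m$sequence), 6L)
  expect_equal(nrow(m$ca), 6L)
  expect_true(all(is.finite(m$ca)))
})

test_that("non-standard residues map to their standard analogue in sequences", {
  fix <- generate_hairpin(3, seed = 6)
  a <- fix$structure$atoms
  a$resid[a$resno == 7] <- "MSE"     # loop residue -> methionine analogue
  s <- structure_model(a, experimental_method = "xray", resolution = 2)
  pair <- find_hairpin_pairs(fix$ss, "A")[[1]]
  m <- extract_loop_motif(s, pair)
  expect_equal(substr(m$sequence, 2, 2), "M")
  expect_equal(aa_one_letter(c("MSE", "SEC", "UNK", "XYZ")),
               c("M", "C", "X", "X"))
})

test_that("immediately adjacent strands raise a no-loop error", {
  # extend the N-terminal strand over the whole intervening region so the
  # two strands touch with no residues in between
  fix <- generate_hairpin(2, seed = 8)
  pair <- find_hairpin_pairs(fix$ss, "A")[[1]]
  pair$n_strand <- fix$ss$key[1:7]
  expect_error(extract_loop_motif(fix$structure, pair), "no loop")
})

test_that("the loop filter counts secondary-structure residues and gaps", {
  fix <- generate_hairpin(6, seed = 10)
  pair <- find_hairpin_pairs(fix$ss, "A")[[1]]
  m <- extract_loop_motif(fix$structure, pair)
  relabel <- function(lab, k) {
    ann <- fix$ss
    idx <- match(m$residues$key, ann$key)
    ann$ss[idx[seq_len(k)]] <- lab
    ann
  }
  expect_true(passes_loop_filter(m, relabel("helix", 3)))    # three allowed
  expect_false(passes_loop_filter(m, relabel("strand", 4)))  # four rejected
  # length window
  expect_false(passes_loop_filter(m, fix$ss,
                                  loop_filter_criteria(min_length = 7)))
  expect_false(passes_loop_filter(m, fix$ss,
                                  loop_filter_criteria(max_length = 5)))
  # numbering gap inside the loop marks it unresolved
  gap <- m
  gap$residues$resno[3:6] <- gap$residues$resno[3:6] + 2L
  expect_false(passes_loop_filter(gap, fix$ss))
  expect_true(passes_loop_filter(gap, fix$ss,
                                 loop_filter_criteria(require_no_gaps = FALSE)))
  # missing CA marks it unresolved
  noca <- m
  noca$ca[2, ] <- NA_real_
  expect_false(passes_loop_filter(noca, fix$ss))
})

test_that("relaxing the loop filter never rejects a previously accepted loop", {
  set.seed(33)
  fix <- generate_hairpin(8, seed = 12)
  pair <- find_hairpin_pairs(fix$ss, "A")[[1]]
  m <- extract_loop_motif(fix$structure, pair)
  ann <- fix$ss
  idx <- match(m$residues$key, ann$key)
  ann$ss[idx[1:2]] <- "helix"
  for (k in 0:4) {
    strict <- passes_loop_filter(m, ann,
                                 loop_filter_criteria(max_ss_residues_in_loop = k))
    relaxed <- passes_loop_filter(m, ann,
                                  loop_filter_criteria(max_ss_residues_in_loop = k + 1))
    expect_true(!strict || relaxed)
  }
})

test_that("mining recovers the generator ground truth for lengths 1 to 30", {
  for (len in c(1:10, 15, 22, 30)) {
    fix <- generate_hairpin(len, seed = 100 + len)
    motifs <- mine_loops(fix$structure, ann = fix$ss,
                         criteria = loop_filter_criteria(max_length = 87))
    expect_length(motifs, 1L)
    expect_equal(motifs[[1]]$residues$key, fix$loop_keys, info = len)
    # flanked by strand labels on both sides
    rt <- residue_table(fix$structure)
    i0 <- match(motifs[[1]]$residues$key[1], rt$key)
    i1 <- match(motifs[[1]]$residues$key[len], rt$key)
    expect_equal(fix$ss$ss[i0 - 1L], "strand")
    expect_equal(fix$ss$ss[i1 + 1L], "strand")
  }
})

mock_fv <- function(cdr_len = 10, entry_id = "FV01") {
  # heavy chain: hairpin whose loop stands in for the CDR3; light chain: a
  # short helix placed nearby
  fix <- generate_hairpin(cdr_len, strand_length = 4, seed = 21,
                          entry_id = entry_id, chain = "H")
  helix <- build_backbone(rep(-57, 8), rep(-47, 8), chain = "L")
  helix[, c("x", "y", "z")] <- helix[, c("x", "y", "z")] + 8
  s <- structure_model(rbind(fix$structure$atoms, helix),
                       entry_id = entry_id, experimental_method = "xray",
                       resolution = 2)
  loop_resno <- 5:(4 + cdr_len)
  numbering <- rbind(
    data.frame(chain = "H", resno = 1:(8 + cdr_len), insert = "",
               imgt = c(103:106, 107:(106 + cdr_len), 117:120)[1:(8 + cdr_len)],
               chain_role = "heavy", stringsAsFactors = FALSE),
    data.frame(chain = "L", resno = 1:8, insert = "",
               imgt = 1:8, chain_role = "light", stringsAsFactors = FALSE))
  numbering$key <- loopflex:::res_key(numbering$chain, numbering$resno,
                                      numbering$insert)
  list(s = s, numbering = numbering, fix = fix)
}

test_that("CDR3 extraction selects IMGT positions 107-116", {
  mv <- mock_fv(10)
  m <- extract_cdr3(mv$s, mv$numbering, "heavy")
  expect_equal(m$loop_length, 10L)
  expect_equal(m$origin, "cdrh3")
  expect_equal(m$residues$resno, 5:14)
  expect_true(nzchar(m$fv_sequence))
  # Fv sequence concatenates heavy then light chains
  h <- paste(residue_table(mv$s)$one[residue_table(mv$s)$chain == "H"],
             collapse = "")
  l <- paste(residue_table(mv$s)$one[residue_table(mv$s)$chain == "L"],
             collapse = "")
  expect_equal(m$fv_sequence, paste0(h, l))
})

test_that("IMGT insertions inside 107-116 are included in the CDR3", {
  mv <- mock_fv(13)
  # positions 107..116 plus insertions 111.1, 111.2, 112.1
  mv$numbering$imgt[mv$numbering$chain_role == "heavy"] <-
    c(103:106, 107, 108, 109, 110, 111, 111.1, 111.2, 112.1, 112,
      113:116, 117:120)[1:21]
  m <- extract_cdr3(mv$s, mv$numbering, "heavy")
  expect_equal(m$loop_length, 13L)
})

test_that("missing numbering and empty ranges raise distinct errors", {
  mv <- mock_fv(10)
  expect_error(extract_cdr3(mv$s, mv$numbering, "beta"), "no IMGT numbering")
  bad <- mv$numbering
  bad$imgt[bad$chain_role == "heavy"] <- 1:18
  expect_error(extract_cdr3(mv$s, bad, "heavy"), "107")
})

test_that("motifs survive the JSON-lines round trip", {
  fix <- generate_hairpin(5, seed = 13)
  motifs <- mine_loops(fix$structure, ann = fix$ss)
  path <- tempfile(fileext = ".jsonl")
  write_motifs_jsonl(motifs, path)
  back <- read_motifs_jsonl(path)
  expect_length(back, length(motifs))
  expect_equal(back[[1]]$sequence, motifs[[1]]$sequence)
  expect_equal(back[[1]]$ca, motifs[[1]]$ca, tolerance = 1e-12)
  expect_equal(back[[1]]$anchors, motifs[[1]]$anchors)
  expect_equal(back[[1]]$origin, motifs[[1]]$origin)
})
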