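test_that("helix-anchored enumeration recovers the offset-10 embedding", {
  pair <- sa_like_pair()
  # long helix at 16-32, short helix at 6-22: offset 10 aligns them exactly,
  # placing the 56-residue domain at positions 11-66
  cand <- enumerate_embeddings(pair$long, pair$short, "α1")
  expect_true(10 %in% cand$offset)
  e10 <- cand$embedding[[which(cand$offset == 10)]]
  expect_equal(e10$start, 11L)
  expect_equal(e10$end, 66L)
  expect_equal(e10$anchor_overlap, 17L)
  # every returned offset satisfies the >= 4 residue anchor-overlap rule
  expect_equal(sort(cand$offset),
               oracle_offsets(pair$long, pair$short, "α1"))
})

test_that("equal-length templates with coincident anchors give exactly offset 0", {
  tm <- fold_template(
    "eq", 30,
    secondary_elements(c("strand", "helix"), c(2, 10), c(6, 20)),
    data.frame(i = 2, j = 12), paste(rep("A", 30), collapse = "")
  )
  cand <- enumerate_embeddings(tm, tm, "α1")
  expect_equal(cand$offset, 0L)
})

test_that("enumeration equals the brute-force offset scan on toy pairs", {
  long <- fold_template(
    "l30", 30,
    secondary_elements(c("helix", "strand"), c(8, 20), c(15, 26)),
    data.frame(i = 8, j = 22), paste(rep("A", 30), collapse = "")
  )
  short <- fold_template(
    "s12", 12,
    secondary_elements("helix", 3, 10),
    data.frame(i = 3, j = 10), paste(rep("A", 12), collapse = "")
  )
  cand <- enumerate_embeddings(long, short, "α1")
  expect_equal(sort(cand$offset), oracle_offsets(long, short, "α1"))
  expect_gt(nrow(cand), 1)
  # anchor label absent is a configuration error, oversized short a domain one
  expect_error(enumerate_embeddings(long, short, "α9"),
               class = "foldswitch_config_error")
  expect_error(enumerate_embeddings(short, long, "α1"),
               class = "foldswitch_domain_error")
})

test_that("conflict scoring applies each rule in the right fold context", {
  # 12-residue toy: position 3 is core in the short fold only
  long <- fold_template(
    "cl", 20,
    secondary_elements(c("strand", "helix"), c(1, 8), c(5, 18)),
    data.frame(i = c(1, 2), j = c(10, 12)),
    paste(rep("A", 20), collapse = "")
  )
  short <- fold_template(
    "cs", 12,
    secondary_elements(c("strand", "helix"), c(1, 6), c(4, 12)),
    data.frame(i = rep(3, 6), j = 6:11),
    paste(rep("A", 12), collapse = "")
  )
  expect_equal(short$burial[3], "core")
  emb <- embedding(long, short, 4, c("α1", "α1"))
  # all-alanine sequence, no core positions in the long fold: no conflicts
  base <- paste(rep("A", 20), collapse = "")
  expect_equal(score_conflicts(emb, long, short, base)$total_count, 0)
  # K at long position 7 = short position 3 (core in short only):
  # exactly one buried_polar attributed to the short context
  seq_k <- base
  substr(seq_k, 7, 7) <- "K"
  rep_k <- score_conflicts(emb, long, short, seq_k)
  expect_equal(rep_k$total_count, 1)
  expect_equal(rep_k$conflicts$kind, "buried_polar")
  expect_equal(rep_k$conflicts$context, "short")
  expect_equal(rep_k$conflicts$position, 7L)
  # P inside the long fold's helix, beyond the embedded window so only the
  # long context sees it: one helix_breaker
  seq_p <- base
  substr(seq_p, 17, 17) <- "P"
  rep_p <- score_conflicts(emb, long, short, seq_p)
  expect_equal(rep_p$conflicts$kind, "helix_breaker")
  expect_equal(rep_p$conflicts$context, "long")
  # severity bookkeeping
  expect_equal(rep_p$total_severity,
               sum(conflict_params()$severity[rep_p$conflicts$kind]))
  expect_error(score_conflicts(emb, long, short, "AAA"),
               class = "foldswitch_domain_error")
})

test_that("a residue incompatible with both folds counts once per context", {
  tm <- fold_template(
    "both", 12,
    secondary_elements(c("strand", "helix"), c(1, 6), c(4, 12)),
    data.frame(i = rep(1, 6), j = 5:10),
    paste(rep("A", 12), collapse = "")
  )
  expect_equal(tm$burial[1], "core")
  emb <- embedding(tm, tm, 0, "α1")
  seq_k <- paste0("K", paste(rep("A", 11), collapse = ""))
  rep_k <- score_conflicts(emb, tm, tm, seq_k)
  expect_equal(rep_k$total_count, 2)
  expect_setequal(rep_k$conflicts$context, c("long", "short"))
})

test_that("surface-to-core mutations never decrease the conflict count", {
  pair <- make_fold_pair(toy_fold_spec(seed = 21))
  d <- merge_initial(pair$truth, pair$long, pair$short)
  rep0 <- score_conflicts(d$embedding, d$long, d$short, d$long_sequence)
  chars <- strsplit(d$long_sequence, "")[[1]]
  core_any <- d$long$burial == "core"
  core_any[d$embedding$start:d$embedding$end] <-
    core_any[d$embedding$start:d$embedding$end] | d$short$burial == "core"
  targets <- which(core_any & chars == "A")
  for (p in utils::head(which(core_any), 5)) {
    mutated <- d$long_sequence
    substr(mutated, p, p) <- "K"
    rep1 <- score_conflicts(d$embedding, d$long, d$short, mutated)
    expect_gte(rep1$total_count, rep0$total_count)
  }
})

test_that("embedding ranking is the documented total order and is stable", {
  mk_report <- function(offset, count, severity, matches) {
    structure(list(
      embedding = list(offset = offset),
      conflicts = NULL, total_count = count, total_severity = severity,
      kind_matches = matches
    ), class = "conflict_report")
  }
  reports <- list(mk_report(3, 3, 1, 1), mk_report(1, 0, 0, 2),
                  mk_report(2, 7, 2, 0))
  ranked <- rank_embeddings(reports)
  expect_equal(ranked$total_count, c(0, 3, 7))
  # tie on count and severity: more kind matches first
  tie <- list(mk_report(5, 2, 1, 1), mk_report(4, 2, 1, 3))
  expect_equal(rank_embeddings(tie)$offset, c(4L, 5L))
  # random reports: order equals an independent sort of the key tuple, and
  # permuting the input never changes the output
  withr::with_seed(5, {
    for (rep in 1:10) {
      rs <- lapply(1:6, function(k) {
        mk_report(k, sample(0:3, 1), sample(0:2, 1), sample(0:3, 1))
      })
      ranked <- rank_embeddings(rs)
      expect_equal(ranked$offset, oracle_rank_order(ranked))
      shuffled <- rank_embeddings(sample(rs))
      expect_equal(shuffled$offset, ranked$offset)
    }
  })
  expect_error(rank_embeddings(list()), class = "foldswitch_domain_error")
})

test_that("the bundled S/A-like fixture pair aligns the two anchor helices", {
  pair <- make_fold_pair(toy_fold_spec(seed = 2))
  ranked <- rank_fold_pair(pair$long, pair$short, pair$anchor)
  top <- ranked$report[[1]]$embedding
  expect_equal(top$offset, pair$truth$offset)
  anchor_corr <- top$correspondences[
    top$correspondences$short_element == pair$anchor, ]
  expect_equal(anchor_corr$long_element, pair$anchor)
  expect_true(anchor_corr$kind_match)
})
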