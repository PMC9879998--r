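test_that("merging threads the short reference inside the long reference", {
  # marker construction: short all-A window inside long all-G frame
  long <- fold_template(
    "lg", 20, secondary_elements("helix", 3, 14),
    data.frame(i = 3, j = 10), paste(rep("G", 20), collapse = "")
  )
  short <- fold_template(
    "sh", 8, secondary_elements("helix", 1, 8),
    data.frame(i = 1, j = 5), paste(rep("A", 8), collapse = "")
  )
  emb <- embedding(long, short, 4, "α1")
  d <- merge_initial(emb, long, short)
  expect_equal(d$long_sequence,
               paste0("GGGG", paste(rep("A", 8), collapse = ""), "GGGGGGGG"))
  expect_equal(nrow(d$mutation_log), 0)
  # offset 0 with equal lengths: merged sequence equals the short reference
  full <- embedding(short, short, 0, "α1")
  expect_equal(merge_initial(full, short, short)$long_sequence,
               short$ref_sequence)
})

test_that("coarse energy is the term-by-term sum and respects symmetries", {
  model <- energy_model()
  # no contacts + zero burial/ss weights: empty sum
  tm0 <- tiny_template(contacts = data.frame(i = integer(0), j = integer(0)))
  m_contact_only <- energy_model(1, 0, 0)
  expect_equal(coarse_energy("VKVAAEELLKKA", tm0, m_contact_only), 0)
  # brute-force summation oracle on random templates/sequences
  for (seed in 1:5) {
    tm <- random_template(sample(12:30, 1), seed)
    sq <- withr::with_seed(seed + 100, paste(
      sample(DESIGN_ALPHABET_TEST, tm$length, replace = TRUE), collapse = ""))
    expect_equal(coarse_energy(sq, tm, model), oracle_energy(sq, tm, model),
                 tolerance = 1e-12)
  }
  # swapping two contact-free residues with equal burial and element context
  # leaves the score unchanged
  tm <- tiny_template(contacts = data.frame(i = 1, j = 8))
  sq1 <- "VKVAAEELLKKA"
  sq2 <- sq1
  substr(sq2, 10, 10) <- "A"   # helix positions 10 and 12, both surface
  substr(sq2, 12, 12) <- "K"
  expect_equal(tm$burial[10], tm$burial[12])
  expect_equal(coarse_energy(sq1, tm), coarse_energy(sq2, tm))
  err <- expect_error(coarse_energy("VKVAAEELLKKZ", tm),
                      class = "foldswitch_domain_error")
  expect_match(conditionMessage(err), "12")
})

test_that("conflict clusters cover conflicts with bounded, connected groups", {
  pair <- make_fold_pair(toy_fold_spec(seed = 4, n_planted_conflicts = 4,
                                       decoy_conflict_floor = 6))
  d <- merge_initial(pair$truth, pair$long, pair$short)
  rep0 <- score_conflicts(d$embedding, d$long, d$short, d$long_sequence)
  expect_equal(rep0$total_count, 4)
  clusters <- find_conflict_clusters(rep0, d)
  expect_true(all(lengths(clusters) <= 6))
  expect_true(all(lengths(clusters) >= 1))
  covered <- unlist(clusters)
  expect_true(all(rep0$conflicts$position %in% covered))
  # a clean design yields no clusters
  clean <- make_fold_pair(toy_fold_spec(seed = 4, n_planted_conflicts = 0,
                                        decoy_conflict_floor = 2))
  dc <- merge_initial(clean$truth, clean$long, clean$short)
  repc <- score_conflicts(dc$embedding, dc$long, dc$short, dc$long_sequence)
  expect_equal(repc$total_count, 0)
  expect_equal(find_conflict_clusters(repc, dc), list())
})

test_that("cluster resolution matches the exhaustive-assignment oracle", {
  small_alphabet <- c("A", "V", "L", "K", "E", "S")
  model <- energy_model()
  withr::with_seed(17, {
    for (rep in 1:6) {
      pair <- make_fold_pair(toy_fold_spec(seed = 30 + rep))
      d <- merge_initial(pair$truth, pair$long, pair$short)
      rep0 <- score_conflicts(d$embedding, d$long, d$short, d$long_sequence)
      pos_pool <- unique(c(rep0$conflicts$position,
                           which(d$long$burial == "core")))
      cluster <- sort(sample(pos_pool, sample(2:3, 1)))
      d2 <- resolve_cluster(d, cluster, model, small_alphabet)
      chosen <- strsplit(d2$long_sequence, "")[[1]][cluster]
      best <- oracle_resolve(d, cluster, small_alphabet, model)
      expect_equal(paste(chosen, collapse = ""), best$str)
      expect_equal(oracle_cluster_conflicts(d, cluster, chosen), best$conf)
    }
  })
})

test_that("already-clean clusters are conserved untouched", {
  pair <- make_fold_pair(toy_fold_spec(seed = 8, n_planted_conflicts = 0,
                                       decoy_conflict_floor = 2))
  d <- merge_initial(pair$truth, pair$long, pair$short)
  cluster <- which(d$long$burial == "core")[1:3]
  d2 <- resolve_cluster(d, cluster)
  expect_identical(d2$long_sequence, d$long_sequence)
  expect_equal(nrow(d2$mutation_log), 0)
})

test_that("a single clean substitution beats any double substitution", {
  # position 7 (short core) holds K; position 8 surface: mutating 7 alone
  # suffices, and conservation must prefer it over any 2-mutation fix
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
  emb <- embedding(long, short, 4, "α1")
  d <- merge_initial(emb, long, short)
  substr(d$long_sequence, 7, 7) <- "K"
  d$initial_sequence <- d$long_sequence
  d2 <- resolve_cluster(d, c(7L, 8L), alphabet = c("A", "V", "L", "K", "E", "S"))
  expect_equal(nrow(d2$mutation_log), 1)
  expect_equal(d2$mutation_log$position, 7L)
  rep2 <- score_conflicts(emb, long, short, d2$long_sequence)
  expect_equal(rep2$total_count, 0)
})

test_that("infeasible clusters return the oracle argmin with a warning", {
  # force infeasibility by restricting the alphabet to buried-polar residues
  long <- fold_template(
    "inf", 16,
    secondary_elements(c("strand", "helix"), c(1, 8), c(5, 16)),
    data.frame(i = rep(2, 6), j = c(8:12, 16)),
    paste(rep("A", 16), collapse = "")
  )
  short <- fold_template(
    "infs", 8, secondary_elements("helix", 2, 8),
    data.frame(i = 2, j = 8), paste(rep("A", 8), collapse = "")
  )
  emb <- embedding(long, short, 8, "α1")
  d <- merge_initial(emb, long, short)
  polar_only <- c("K", "E", "N")
  substr(d$long_sequence, 2, 2) <- "K"
  d$initial_sequence <- d$long_sequence
  expect_warning(
    d2 <- resolve_cluster(d, 2L, alphabet = polar_only),
    "infeasible"
  )
  chosen <- substr(d2$long_sequence, 2, 2)
  best <- oracle_resolve(d, 2L, polar_only, energy_model())
  expect_equal(chosen, best$str)
})

test_that("oversized clusters are rejected", {
  pair <- make_fold_pair(toy_fold_spec(seed = 2))
  d <- merge_initial(pair$truth, pair$long, pair$short)
  expect_error(resolve_cluster(d, 1:7), class = "foldswitch_domain_error")
})

test_that("non-overlap optimization lowers energy without touching the window", {
  pair <- make_fold_pair(toy_fold_spec(seed = 5))
  d <- resolve_all_conflicts(merge_initial(pair$truth, pair$long, pair$short))
  window_before <- truncate_to_short(d)
  e_before <- coarse_energy(d$long_sequence, d$long)
  d2 <- optimize_nonoverlap(d)
  expect_identical(truncate_to_short(d2), window_before)
  e_after <- coarse_energy(d2$long_sequence, d2$long)
  expect_lte(e_after, e_before)
  # the recorded trajectory is monotone non-increasing
  expect_true(all(diff(d2$optimization$energy_trajectory) <= 1e-9))
  # no new conflicts were introduced
  rep_before <- score_conflicts(d$embedding, d$long, d$short, d$long_sequence)
  rep_after <- score_conflicts(d2$embedding, d2$long, d2$short, d2$long_sequence)
  expect_lte(rep_after$total_count, rep_before$total_count)
  # idempotence at the fixed point
  d3 <- optimize_nonoverlap(d2)
  expect_identical(d3$long_sequence, d2$long_sequence)
  # all positions inside the window: nothing to search
  full <- embedding(pair$short, pair$short, 0, pair$anchor)
  df <- merge_initial(full, pair$short, pair$short)
  expect_identical(optimize_nonoverlap(df)$long_sequence, df$long_sequence)
})

test_that("variants validate the reference residue and flag window membership", {
  pair <- make_fold_pair(toy_fold_spec(seed = 2))
  d <- merge_initial(pair$truth, pair$long, pair$short)
  inside <- d$embedding$start + 4L
  outside <- d$embedding$end + 2L
  cur_in <- substr(d$long_sequence, inside, inside)
  cur_out <- substr(d$long_sequence, outside, outside)
  to_in <- setdiff(c("L", "V", "I"), cur_in)[1]
  to_out <- setdiff(c("R", "K"), cur_out)[1]
  d2 <- apply_variant(d, tibble::tibble(position = inside, from = cur_in,
                                        to = to_in), name = "v1")
  expect_equal(d2$name, "v1")
  expect_true(d2$mutation_log$in_window[1])
  # the derived short construct changed with it
  expect_false(identical(truncate_to_short(d2), truncate_to_short(d)))
  d3 <- apply_variant(d2, tibble::tibble(position = outside, from = cur_out,
                                         to = to_out))
  expect_false(utils::tail(d3$mutation_log$in_window, 1))
  expect_identical(truncate_to_short(d3), truncate_to_short(d2))
  # stale coordinates are rejected
  expect_error(
    apply_variant(d, tibble::tibble(position = inside, from = "Z", to = "A")),
    class = "foldswitch_domain_error"
  )
  # compact mutation syntax and the empty variant
  d4 <- apply_variant(d, character(0), name = "copy")
  expect_identical(d4$long_sequence, d$long_sequence)
  expect_equal(d4$name, "copy")
  d5 <- apply_variant(d, sprintf("%s%d%s", cur_in, inside, to_in))
  expect_identical(d5$long_sequence, d2$long_sequence)
})

test_that("truncation extracts exactly the embedded window", {
  pair <- sa_like_pair()
  emb <- embedding(pair$long, pair$short, 10, "α1")
  d <- merge_initial(emb, pair$long, pair$short)
  expect_equal(truncate_to_short(d), substr(d$long_sequence, 11, 66))
  expect_equal(nchar(truncate_to_short(d)), 56)
  # offset-0 embedding of a 56-in-91 design takes the first 56 residues
  long91 <- fold_template(
    "l91", 91, secondary_elements("helix", 10, 26),
    data.frame(i = 10, j = 30), paste(rep("A", 91), collapse = "")
  )
  short56 <- fold_template(
    "s56", 56, secondary_elements("helix", 10, 26),
    data.frame(i = 10, j = 30), paste(rep("A", 56), collapse = "")
  )
  emb0 <- embedding(long91, short56, 0, "α1")
  d0 <- merge_initial(emb0, long91, short56)
  expect_equal(truncate_to_short(d0), substr(d0$long_sequence, 1, 56))
})

test_that("C-terminal tail grafts replace and append correctly", {
  sq <- paste0(paste(rep("G", 92), collapse = ""), "AAD")
  out <- graft_cterminal_tail(sq, 3, "DKLYRAL")
  expect_equal(nchar(out), 99)
  expect_equal(substr(out, 93, 99), "DKLYRAL")
  sq2 <- paste0(paste(rep("G", 88), collapse = ""), "VTE")
  expect_equal(substr(graft_cterminal_tail(sq2, 3, "DKLYRAL"), 89, 95),
               "DKLYRAL")
  expect_equal(graft_cterminal_tail("AK", 0, "Y"), "AKY")
  expect_error(graft_cterminal_tail("AK", 3, "Y"),
               class = "foldswitch_domain_error")
  expect_error(graft_cterminal_tail("AK", 1, ""),
               class = "foldswitch_domain_error")
})

test_that("mutation logs replay byte-for-byte through all stages", {
  for (seed in c(3, 9)) {
    pair <- make_fold_pair(toy_fold_spec(seed = seed))
    d <- merge_initial(pair$truth, pair$long, pair$short)
    d <- resolve_all_conflicts(d)
    d <- optimize_nonoverlap(d, max_sweeps = 3)
    p <- d$embedding$start + 2L
    cur <- substr(d$long_sequence, p, p)
    to <- setdiff(c("V", "L", "I"), cur)[1]
    d <- apply_variant(d, tibble::tibble(position = p, from = cur, to = to))
    d <- graft_cterminal_tail(d, 2, "DKLYRAL")
    expect_identical(replay_mutations(d), d$long_sequence)
    expect_setequal(unique(d$mutation_log$stage),
                    intersect(c("cluster", "nonoverlap", "variant", "tail_graft"),
                              d$mutation_log$stage))
  }
})

test_that("percent identity reports raw and rounded values symmetrically", {
  a <- paste(rep("A", 56), collapse = "")
  b <- a
  substr(b, 5, 5) <- "L"
  one_off <- percent_identity(a, b)
  expect_equal(one_off$identity, 100 * 55 / 56, tolerance = 1e-12)
  expect_equal(one_off$identity_rounded, 98)
  expect_equal(percent_identity(a, a)$identity, 100)
  expect_equal(percent_identity("AAAA", "GGGG")$identity, 0)
  # symmetry and invariance to consistent relabeling
  expect_equal(percent_identity(a, b)$identity, percent_identity(b, a)$identity)
  a2 <- chartr("AL", "VW", a)
  b2 <- chartr("AL", "VW", b)
  expect_equal(percent_identity(a2, b2)$identity, one_off$identity)
  expect_error(percent_identity("AA", "AAA"), class = "foldswitch_domain_error")
})
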