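test_that("replicate merge applies the both-present rule cell-wise", {
  tb <- tiny_table()
  m <- merge_replicates(tb)
  # (3,4) -> 7; (0,7) -> 0; (10,10) -> 20; (5,6) -> 11
  expect_identical(m$counts[, c("s1", "s2")],
                   rbind(OTU1 = c(s1 = 7L, s2 = 0L),
                         OTU2 = c(s1 = 20L, s2 = 11L),
                         OTU3 = c(s1 = 0L, s2 = 0L)))
  # negatives pass through unmerged
  expect_identical(m$counts[, c("n1", "n2")], tb$counts[, c("n1", "n2")])

  # replicate B all zero -> merged table all zero
  z <- otu_table(rbind(O1 = c(a = 5L, b = 0L), O2 = c(a = 9L, b = 0L)),
                 replicate_pairs = data.frame(sample_id = "s", lib_a = "a",
                                              lib_b = "b"))
  expect_true(all(merge_replicates(z)$counts == 0L))

  # merged reads <= sum of replicate reads, equality iff nothing was zeroed
  expect_lte(sum(m$counts[, c("s1", "s2")]),
             sum(tb$counts[, c("a1", "b1", "a2", "b2")]))

  # unpaired library is a configuration error
  bad <- otu_table(rbind(O1 = c(a = 1L, b = 2L, c = 3L)),
                   negative_ids = character())
  bad$replicate_pairs <- data.frame(sample_id = "s", lib_a = "a", lib_b = "b")
  expect_error(merge_replicates(bad), "unpaired")
})

test_that("negative subtraction removes the per-OTU negative maximum", {
  counts <- rbind(O1 = c(s1 = 10L, s2 = 5L, s3 = 3L, n1 = 2L, n2 = 4L),
                  O2 = c(s1 = 8L, s2 = 0L, s3 = 1L, n1 = 0L, n2 = 0L),
                  O3 = c(s1 = 0L, s2 = 0L, s3 = 0L, n1 = 5L, n2 = 9L))
  tb <- otu_table(counts, negative_ids = c("n1", "n2"))
  out <- subtract_negatives(tb)
  expect_identical(out$counts,
                   rbind(O1 = c(s1 = 6L, s2 = 1L, s3 = 0L),
                         O2 = c(s1 = 8L, s2 = 0L, s3 = 1L),
                         O3 = c(s1 = 0L, s2 = 0L, s3 = 0L)))
  # all-zero negatives leave samples unchanged; negatives are dropped
  tb0 <- otu_table(rbind(O1 = c(s = 4L, n = 0L)), negative_ids = "n")
  expect_identical(subtract_negatives(tb0)$counts, rbind(O1 = c(s = 4L)))
  # second application with no negatives is the identity (with a warning)
  expect_warning(again <- subtract_negatives(out), "no negative")
  expect_identical(again$counts, out$counts)
})

test_that("stop-codon screen agrees with a Biostrings translation oracle", {
  # constructed cases: all-sense frame 1 kept; stops in all frames removed
  sense <- paste(rep("ATT", 68), collapse = "")
  allstop <- paste0(paste(rep("ATT", 10), collapse = ""), "TAAATAAATAAA",
                    paste(rep("GGC", 30), collapse = ""))
  ann <- otu_annotations(c("keep", "drop"), c(sense, allstop),
                         class = "Insecta")
  scr <- screen_stop_codons(ann)
  expect_identical(scr$kept, "keep")
  expect_identical(scr$removed, "drop")

  # fuzz: random 205-mers vs independent 3-frame translation via Biostrings
  set.seed(42)
  seqs <- vapply(1:1000, function(i) random_acgt(205), "")
  ann <- otu_annotations(sprintf("O%04d", 1:1000), seqs, class = "Insecta")
  mine <- sprintf("O%04d", 1:1000) %in% screen_stop_codons(ann)$kept
  oracle <- bios_any_frame_stop_free(seqs)
  expect_identical(mine, oracle)
  expect_gt(sum(!mine), 0)  # the fuzz actually exercises removals
})

test_that("N-containing codons are treated as non-stop", {
  ann <- otu_annotations("x", paste0("TNA", paste(rep("ATT", 20), collapse = "")))
  expect_identical(screen_stop_codons(ann)$kept, "x")
  # stops in all three frames plus a non-ACGTN character
  ann2 <- data.frame(otu_id = "y",
                     sequence = paste0("ATR", "TAAATAAATAAA",
                                       paste(rep("ATT", 10), collapse = "")),
                     stringsAsFactors = FALSE)
  expect_warning(out <- screen_stop_codons(ann2), "non-nucleotide")
  expect_identical(out$removed, "y")
})

test_that("dataset split counts named and insect OTUs", {
  counts <- matrix(1L, 5, 2, dimnames = list(paste0("O", 1:5), c("s1", "s2")))
  tb <- otu_table(counts)
  ann <- otu_annotations(paste0("O", 1:5), rep("ATTATT", 5),
                         class = c("Insecta", "Insecta", "Arachnida",
                                   "Insecta", "Insecta"),
                         genus = c("Aus", "", "Bus", "", "Cus"),
                         species = c("Aus bus", "", "Bus cus", "", "Cus dus"))
  ds <- split_datasets(tb, ann)
  expect_identical(rownames(ds$species$counts), c("O1", "O3", "O5"))
  expect_identical(rownames(ds$insects$counts), c("O1", "O2", "O4", "O5"))
  expect_error(split_datasets(otu_table(rbind(OX = c(s1 = 1L, s2 = 1L))), ann),
               "OX")
})

test_that("species-name hygiene keeps clean binomials only", {
  res <- clean_species_names(c("Apis mellifera", "Megaselia sp. BOLD:ACX1234",
                               "Phora sp.4", "Aedes albopictus",
                               "Xénos vésperi", "Aus bus cus",
                               "Genus", "Aus-bus cus"))
  expect_setequal(res$kept, c("Apis mellifera", "Aedes albopictus",
                              "Xénos vésperi"))
  expect_true("Phora sp.4" %in% res$dropped)
  # hyphenated epithets pass only under the documented switch
  expect_identical(clean_species_names("Aus bus-cus", allow_hyphen = TRUE)$kept,
                   "Aus bus-cus")
  expect_identical(clean_species_names("Aus bus-cus")$dropped, "Aus bus-cus")
})

test_that("species merge sums reads and conserves them within groups", {
  counts <- rbind(O1 = c(s1 = 5L, s2 = 0L), O2 = c(s1 = 2L, s2 = 3L),
                  O3 = c(s1 = 1L, s2 = 1L))
  tb <- otu_table(counts)
  ann <- otu_annotations(c("O1", "O2", "O3"), rep("ATT", 3),
                         class = "Insecta", order = "Diptera",
                         family = "Phoridae", genus = "Aus",
                         species = c("Aus bus", "Aus bus", "Aus cus"))
  st <- merge_by_species(tb, ann)
  expect_identical(st$counts["Aus bus", ], c(s1 = 7L, s2 = 3L))
  expect_identical(st$otus_per_species, c("Aus bus" = 2L, "Aus cus" = 1L))

  # brute-force conservation oracle on a random fixture
  set.seed(1)
  n <- 40
  cnt <- matrix(rpois(n * 6, 4), n, 6,
                dimnames = list(sprintf("O%02d", 1:n), paste0("s", 1:6)))
  sp <- paste("Aus", sample(letters[1:8], n, TRUE))
  ann <- otu_annotations(rownames(cnt), rep("ATT", n), class = "Insecta",
                         order = "Diptera", family = "F", genus = "Aus",
                         species = sp)
  st <- merge_by_species(otu_table(cnt), ann)
  for (g in rownames(st$counts)) {
    expect_equal(unname(st$counts[g, ]),
                 unname(colSums(cnt[sp == g, , drop = FALSE])),
                 ignore_attr = TRUE, label = g)
  }
  expect_identical(sum(st$counts), sum(cnt))
})
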