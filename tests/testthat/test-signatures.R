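short_params <- function(...) signature_params(min_len = 3, max_len = 3, ...)

test_that("window_consensus unions target symbols and refuses gapped windows", {
  aln <- toy_aln(c(t1 = "aagta", t2 = "atgta", o1 = "ccccc"),
                 species = c("spT", "spT", "spO"))
  expect_identical(window_consensus(aln, "spT", 1:3), "awg")
  expect_identical(window_consensus(aln, "spT", 1:1), "a")
  gapped <- toy_aln(c(t1 = "a-gta", t2 = "atgta", o1 = "ccccc"),
                    species = c("spT", "spT", "spO"))
  expect_true(is.na(window_consensus(gapped, "spT", 1:3)))
})

test_that("mismatch_count applies IUPAC compatibility and counts gaps", {
  aln <- toy_aln(c(x = "tatcattaag", y = "tatcattaac", z = "tt--------"),
                 species = c("s1", "s2", "s3"))
  expect_equal(mismatch_count("tatcattaag", aln, "x", 1:10), 0L)
  expect_equal(mismatch_count("tatcattaag", aln, "y", 1:10), 1L)
  expect_equal(mismatch_count("aw", aln, "z", 1:2), 1L)  # w~t; a vs t differs
  expect_equal(mismatch_count("aa", aln, "z", 3:4), 2L)  # gaps mismatch
  expect_error(mismatch_count("aaa", aln, "x", 1:2), "window shape")
})

test_that("allowed mismatches derive m = d_min - 1", {
  aln <- toy_aln(c(t1 = "aaaaa", n1 = "aaaat", n3 = "aattt"),
                 species = c("spT", "spN1", "spN3"))
  one_away <- allowed_mismatches("aaaaa", aln, "spT", 1:5)
  expect_equal(one_away$d_min, 1L)
  expect_equal(one_away$m, 0L)
  expect_true(one_away$valid)
  aln2 <- toy_aln(c(t1 = "aaaaa", n3 = "aattt"),
                  species = c("spT", "spN3"))
  three_away <- allowed_mismatches("aaaaa", aln2, "spT", 1:5)
  expect_equal(three_away$m, 2L)
  set.seed(31)
  for (rep in 1:20) {
    aln3 <- random_aln(6, 30, gap_rate = 0.05, amb_rate = 0.1)
    cols <- 5:14
    motif <- paste(sample(c("a", "c", "g", "t", "r", "y"), 10,
                          replace = TRUE), collapse = "")
    got <- allowed_mismatches(motif, aln3, "sp01", cols)
    others <- aln3$taxonomy$id[aln3$taxonomy$species != "sp01"]
    want <- min(vapply(others, function(id) {
      sum(vapply(seq_along(cols), function(j) {
        y <- aln_chars(aln3, id)[cols[j]]
        y == "-" || !oracle_compatible(substr(motif, j, j), y)
      }, logical(1)))
    }, integer(1)))
    expect_equal(got$d_min, want)
  }
})

test_that("find_signatures returns nothing when a non-target mirrors the target", {
  aln <- toy_aln(c(t1 = "acgtacgtac", o1 = "acgtacgtac", o2 = "ttttacgtac"),
                 species = c("spT", "spO1", "spO2"))
  expect_length(find_signatures(aln, "spT", short_params()), 0L)
})

test_that("a single discriminating column yields the expected best window", {
  # target differs from both others at exactly column 5
  aln <- toy_aln(c(t1 = "acgtAcgtac", o1 = "acgtgcgtac", o2 = "acgtgcgtac"),
                 species = c("spT", "spO1", "spO2"))
  sigs <- find_signatures(aln, "spT", short_params())
  # hand enumeration: qualifying 3-windows are those covering column 5
  expect_length(sigs, 3L)
  for (s in sigs) {
    expect_true(s$columns[[1]][1] <= 5 && s$columns[[1]][2] >= 5)
    expect_equal(s$m, 0L)
    expect_equal(s$d_min, 1L)
  }
  # leftmost qualifying window ranks first under equal d_min/ambiguity
  expect_equal(sigs[[1]]$columns[[1]], c(3L, 5L))
})

test_that("search equals brute-force enumeration on random alignments", {
  set.seed(17)
  for (rep in 1:15) {
    aln <- random_aln(sample(4:8, 1), 60, gap_rate = 0.04, amb_rate = 0.04,
                      regions = data.frame(region = c("ITS2", "LSU"),
                                           start = c(1L, 31L),
                                           end = c(30L, 60L)))
    params <- signature_params(min_len = 6, max_len = 8, max_ambiguous = 2)
    got <- signatures_as_data_frame(find_signatures(aln, "sp01", params))
    want <- oracle_signatures(aln, "sp01", params)
    key <- function(df) {
      if (!nrow(df)) return(character(0))
      sort(sprintf("%s:%d:%d:%s:%d:%d", df$region, df$start,
                   if ("len" %in% names(df)) df$len else df$end - df$start + 1L,
                   df$motif, df$d_min, df$ambiguity))
    }
    got$d_min <- got$m + got$margin
    expect_identical(key(got), key(want))
  }
})

test_that("ranking is by d_min, then ambiguity, then region priority", {
  sigs_ord <- function(aln, target, params) {
    df <- signatures_as_data_frame(find_signatures(aln, target, params))
    df$d_min <- df$m + df$margin
    df
  }
  set.seed(23)
  aln <- random_aln(6, 60, gap_rate = 0.02, amb_rate = 0.08,
                    regions = data.frame(region = c("ITS2", "LSU"),
                                         start = c(1L, 31L),
                                         end = c(30L, 60L)))
  df <- sigs_ord(aln, "sp01", signature_params(min_len = 6, max_len = 7))
  if (nrow(df) > 1) {
    pri <- match(df$region, c("ITS2", "LSU"))
    keys <- order(-df$d_min, df$ambiguity, pri, df$start,
                  df$end - df$start + 1L)
    expect_identical(keys, seq_len(nrow(df)))
  }
})

test_that("search is deterministic", {
  set.seed(5)
  aln <- random_aln(8, 80)
  p <- signature_params(min_len = 8, max_len = 10)
  expect_identical(signatures_as_data_frame(find_signatures(aln, "sp01", p)),
                   signatures_as_data_frame(find_signatures(aln, "sp01", p)))
})

test_that("disjunctive search separates a two-subclade target", {
  # two internally uniform target subclades; no single 4-window with <= 2
  # ambiguities separates both from the non-targets
  aln <- toy_aln(
    c(t1 = "ggcaaagg", t2 = "ggcaaagg",   # subclade 1
      t3 = "ttgccctt", t4 = "ttgccctt",   # subclade 2
      o1 = "ggacactt", o2 = "ttgaaagg"),  # each near one subclade
    species = c("spT", "spT", "spT", "spT", "spO1", "spO2"))
  params <- signature_params(min_len = 8, max_len = 8, max_ambiguous = 2,
                             max_alternatives = 3)
  expect_length(find_signatures(aln, "spT", params), 0L)
  sig <- find_disjunctive_signature(aln, "spT", params)
  expect_false(is.null(sig))
  expect_setequal(sig$alternatives, c("ggcaaagg", "ttgccctt"))
  # exhaustive check on this window: o1 best = 4 (vs alt2), o2 best = 3
  # (vs alt1), so d_min = 3 and m = 2
  expect_equal(sig$d_min, 3L)
  expect_equal(sig$m, 2L)
  rep <- verify_signature(aln, sig)
  expect_true(rep$valid)
  expect_gte(rep$margin, 1L)
})

test_that("disjunctive search collapses to one motif for a uniform target", {
  aln <- toy_aln(c(t1 = "aaaacccc", t2 = "aaaacccc", o1 = "ttttgggg"),
                 species = c("spT", "spT", "spO"))
  params <- signature_params(min_len = 8, max_len = 8)
  sig <- find_disjunctive_signature(aln, "spT", params)
  expect_length(sig$alternatives, 1L)
  single <- find_signatures(aln, "spT", params)[[1]]
  expect_identical(sig$alternatives, single$alternatives)
  expect_identical(sig$m, single$m)
})

test_that("disjunctive search refuses an unseparable non-target", {
  aln <- toy_aln(
    c(t1 = "aaaatttt", t2 = "ccccgggg", o1 = "aaaatttt"),
    species = c("spT", "spT", "spO"))
  params <- signature_params(min_len = 8, max_len = 8, max_ambiguous = 8)
  expect_null(find_disjunctive_signature(aln, "spT", params))
})

test_that("verification reports violations after tampering", {
  set.seed(3)
  aln <- random_aln(6, 60, n_species = 6, gap_rate = 0)
  sigs <- find_signatures(aln, "sp01", signature_params(min_len = 8,
                                                        max_len = 8))
  skip_if(length(sigs) == 0, "no signature in this random draw")
  sig <- sigs[[1]]
  rep <- verify_signature(aln, sig)
  expect_true(rep$valid)
  expect_equal(rep$min_nontarget_mismatches, sig$m + rep$margin)
  # overwrite one non-target with the motif inside the window
  cols <- seq.int(sig$columns[[1]][1], sig$columns[[1]][2])
  bad_id <- aln$taxonomy$id[aln$taxonomy$species != "sp01"][1]
  seqs <- aln$seqs
  chars <- strsplit(seqs[[bad_id]], "")[[1]]
  motif_chars <- strsplit(sig$alternatives[[1]], "")[[1]]
  chars[cols] <- vapply(motif_chars, function(cc) iupac_expansion(cc)[1], "")
  seqs[[bad_id]] <- paste(chars, collapse = "")
  tampered <- toy_aln(seqs, species = aln$taxonomy$species)
  rep2 <- verify_signature(tampered, sig)
  expect_false(rep2$valid)
  expect_true(bad_id %in% rep2$offending)
})

test_that("published-style signatures validate on embedded contrasts", {
  # paper-format record: motif + "no mismatch allowed" (m = 0); embed a
  # target carrying it exactly and non-targets one substitution away
  aln <- toy_aln(
    c(t1 = "gtatcattaagc", t2 = "gtatcattaagc",
      o1 = "gtatcatgaagc", o2 = "gtttcattaagc"),
    species = c("spT", "spT", "spO1", "spO2"))
  sig <- list(target = "spT", alternatives = "tatcattaag",
              columns = list(c(2L, 11L)), m = 0L)
  rep <- verify_signature(aln, sig)
  expect_true(rep$all_targets_match)
  expect_true(rep$valid)
  expect_equal(rep$min_nontarget_mismatches, 1L)
})

test_that("adding a non-target can only lower m; removing can only raise it", {
  set.seed(8)
  aln <- random_aln(7, 50, n_species = 7, gap_rate = 0)
  motif <- window_consensus(aln, "sp01", 11:20)
  skip_if(is.na(motif))
  base <- allowed_mismatches(motif, aln, "sp01", 11:20)
  shrunk_ids <- aln$taxonomy$id[-nrow(aln$taxonomy)]
  shrunk <- toy_aln(aln$seqs[shrunk_ids],
                    species = aln$taxonomy$species[-nrow(aln$taxonomy)])
  fewer <- allowed_mismatches(motif, shrunk, "sp01", 11:20)
  expect_gte(fewer$d_min, base$d_min)
  grown <- toy_aln(c(aln$seqs, extra = aln$seqs[["seq02"]]),
                   species = c(aln$taxonomy$species, "spX"))
  more <- allowed_mismatches(motif, grown, "sp01", 11:20)
  expect_lte(more$d_min, base$d_min)
})
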