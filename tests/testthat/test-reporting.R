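ledger_path <- function() {
  system.file("extdata", "new_taxon_ledger.tsv", package = "sigtax")
}

mini_ledger <- function() {
  validate_taxon_ledger(data.frame(
    phylum = c("P1", "P1", "P2"),
    phylum_status = c("described", "described", "new"),
    class = c("C1", "C1", "C2"),
    class_status = c("new", "new", "new"),
    order = c("O1", "O2", "O3"),
    order_status = c("new", "new", "new"),
    family = c("F1", "F2", "F3"),
    family_status = c("new", "new", "new"),
    genus = c("G1", "G2", "G3"),
    genus_status = c("new", "new", "new"),
    species = c("G1 a", "G2 b", "G3 c"),
    species_status = c("new", "combination", "new"),
    stringsAsFactors = FALSE))
}

test_that("new-taxon counts deduplicate names and honour status flags", {
  led <- mini_ledger()
  expect_equal(count_new_taxa(led, "phylum"), 1L)   # P1 described
  expect_equal(count_new_taxa(led, "class"), 2L)    # C1 shared by two rows
  expect_equal(count_new_taxa(led, "order"), 3L)
  expect_equal(count_new_taxa(led, "species"), 2L)  # combination excluded
  expect_error(count_new_taxa(led, "kingdom"), "bad rank")
})

test_that("one all-new row counts once at every rank", {
  led <- validate_taxon_ledger(data.frame(
    phylum = "P", phylum_status = "new", class = "C", class_status = "new",
    order = "O", order_status = "new", family = "F", family_status = "new",
    genus = "G", genus_status = "new", species = "G s",
    species_status = "new", stringsAsFactors = FALSE))
  for (r in c("phylum", "class", "order", "family", "genus", "species")) {
    expect_equal(count_new_taxa(led, r), 1L)
  }
  expect_equal(distinct_highest_rank_lineages(led), 1L)
})

test_that("highest-rank lineages pick the deepest novel rank per row", {
  led <- mini_ledger()
  # rows 1-2 share novel class C1; row 3 is a novel phylum
  expect_equal(distinct_highest_rank_lineages(led), 2L)
  none_new <- led
  none_new$class_status[1] <- "described"
  none_new$order_status[1] <- "described"
  none_new$family_status[1] <- "described"
  none_new$genus_status[1] <- "described"
  none_new$species_status[1] <- "described"
  expect_warning(n <- distinct_highest_rank_lineages(none_new),
                 "no novel rank")
  expect_equal(n, 2L)
})

test_that("dedup never increases per-rank tallies above the row sums", {
  led <- read_taxon_ledger(ledger_path())
  for (r in c("phylum", "class", "order", "family", "genus", "species")) {
    row_sum <- sum(led[[paste0(r, "_status")]] == "new")
    expect_lte(count_new_taxa(led, r), row_sum)
  }
})

test_that("the packaged ledger reproduces the published per-rank totals", {
  led <- read_taxon_ledger(ledger_path())
  expect_equal(count_new_taxa(led, "phylum"), 8L)
  expect_equal(count_new_taxa(led, "class"), 27L)
  expect_equal(count_new_taxa(led, "order"), 31L)
  expect_equal(count_new_taxa(led, "family"), 31L)
  expect_equal(count_new_taxa(led, "genus"), 31L)
  expect_equal(distinct_highest_rank_lineages(led), 30L)
  # the class tally genuinely exercises dedup + exclusion: 30 distinct class
  # names across rows, 3 of them previously described
  expect_equal(length(unique(led$class)), 30L)
  expect_equal(length(unique(led$class[led$class_status == "described"])), 3L)
})

test_that("mismatch budgets render as number-words and re-parse", {
  expect_match(sigtax:::mismatch_phrase(0), "^no mismatch allowed$")
  expect_match(sigtax:::mismatch_phrase(1), "^one mismatch allowed$")
  expect_match(sigtax:::mismatch_phrase(2), "^two mismatches allowed$")
  expect_match(sigtax:::mismatch_phrase(3), "^three mismatches allowed$")
  expect_warning(txt <- sigtax:::mismatch_phrase(5), "exceeds three")
  expect_identical(txt, "5 mismatches allowed")
  for (m in 0:3) {
    expect_equal(sigtax:::parse_mismatch_phrase(sigtax:::mismatch_phrase(m)),
                 m)
  }
})

test_that("diagnosis rendering follows the conventional wording", {
  dists <- data.frame(region = c("ITS2", "LSU"),
                      max_intra = c(0.038, 0.015),
                      min_inter = c(0.101, 0.062),
                      barcode_gap = c(TRUE, TRUE))
  txt <- render_diagnosis(
    "Pantelleria saittana", "Pantelleria",
    signatures = list(list(region = "ITS2", positions = "131–155",
                           motif = "tttacatctttttctaaacttaatc", m = 1L)),
    distances = dists,
    clade = list(parent = "Pantelleriales", ids = c("EUK1", "EUK2")))
  expect_match(txt, "one mismatch allowed", fixed = TRUE)
  expect_match(txt, "Intraspecific variation up to 3.8% in ITS2", fixed = TRUE)
  expect_match(txt, "Interspecific distance at least 10.1% in ITS2",
               fixed = TRUE)
  expect_match(txt, "Forms a monophyletic, least inclusive clade in",
               fixed = TRUE)
  expect_match(txt, "EUK1 and EUK2", fixed = TRUE)
  no_gap <- dists
  no_gap$barcode_gap[1] <- FALSE
  txt2 <- render_diagnosis("X y", "X",
                           signatures = list(list(region = "ITS2",
                                                  positions = "1–20",
                                                  motif = "acgtacgtacgtacgtacgt",
                                                  m = 0L)),
                           distances = no_gap,
                           clade = list(parent = "Z", ids = "i1"))
  expect_match(txt2, "no mismatch allowed", fixed = TRUE)
  expect_match(txt2, "there is no clear barcode gap in ITS2", fixed = TRUE)
})

test_that("render -> parse -> render is a fixed point", {
  dists <- data.frame(region = c("ITS2", "LSU"),
                      max_intra = c(0.021, 0.006),
                      min_inter = c(0.118, 0.069),
                      barcode_gap = c(TRUE, FALSE))
  sigs <- list(
    list(region = "ITS2", positions = "99–118 in type species",
         motif = "tttctataatatttttgaca", m = 1L),
    list(region = "LSU",
         positions = "614–633 in type species and 615–634 in Scer",
         motif = "ggcaagccgggcaaa OR ggctgctcggacaaa", m = 2L))
  txt <- render_diagnosis("Edaphochytrium valuojaense", "Edaphochytrium",
                          sigs, dists,
                          list(parent = "Edaphochytriales",
                               ids = c("EUK1", "EUK2", "EUK3")))
  parsed <- parse_diagnosis(txt)
  expect_identical(parsed$genus, "Edaphochytrium")
  expect_length(parsed$signatures, 2L)
  expect_identical(parsed$signatures[[2]]$motif,
                   "ggcaagccgggcaaa OR ggctgctcggacaaa")
  expect_identical(parsed$signatures[[1]]$positions,
                   "99–118 in type species")
  expect_equal(parsed$signatures[[2]]$m, 2L)
  expect_equal(unname(parsed$max_intra["ITS2"]), 0.021)
  expect_equal(unname(parsed$min_inter["LSU"]), 0.069)
  expect_identical(parsed$no_gap_regions, "LSU")
  expect_identical(parsed$clade$ids, c("EUK1", "EUK2", "EUK3"))
  txt2 <- render_diagnosis(
    "Edaphochytrium valuojaense", parsed$genus, parsed$signatures,
    data.frame(region = names(parsed$max_intra),
               max_intra = unname(parsed$max_intra),
               min_inter = unname(parsed$min_inter),
               barcode_gap = !names(parsed$max_intra) %in%
                 parsed$no_gap_regions),
    parsed$clade)
  expect_identical(txt2, txt)
})

test_that("an end-to-end diagnosis assembles from pipeline objects", {
  sim <- simulate_taxon_set(synthetic_config(
    seed = 14, n_species = 4, reads_per_species = c(3, 4),
    region_lengths = c(ITS2 = 300, LSU = 400), repeat_noise = FALSE,
    planted = list(list(taxon = "Species_01", region = "ITS2", len = 20L,
                        k = 3L))))
  aln <- sim$alignment
  sigs <- find_signatures(aln, "Species_01")
  dists <- distance_report(aln, "Species_01", c("ITS2", "LSU"))
  legitype <- aln$taxonomy$id[aln$taxonomy$roles == "legitype" &
                                aln$taxonomy$species == "Species_01"]
  # a planted signature can carry a double-digit budget, rendered as digits
  txt <- suppressWarnings(diagnosis_from_results(
    aln, sigs[1], dists, "Simulales",
    clade_ids = aln$taxonomy$id[aln$taxonomy$species == "Species_01"],
    coord_systems = list(ITS2 = list(
      coordinate_system(legitype, "ITS2", label = "type species")))))
  parsed <- parse_diagnosis(txt)
  expect_identical(parsed$genus, "Genus_01")
  expect_match(parsed$signatures[[1]]$positions, "in type species")
  expect_identical(parsed$signatures[[1]]$motif, sigs[[1]]$alternatives[[1]])
})
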