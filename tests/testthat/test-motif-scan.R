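test_that("find_kinase_domain recovers a planted domain", {
  seq <- plant_domain(pre = "MKTAG", loop = strrep("Q", 10), triplet = "TEY",
                      spacer = "LMNKLA")
  rec <- protein_records("p1", seq)
  ann <- find_kinase_domain(rec)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$triplet, "TEY")
  expect_equal(ann$n_start, 6L)
  expect_equal(ann$n_end, 12L)
  expect_equal(ann$triplet_start, 23L)
  expect_equal(ann$c_start, 32L)
  expect_true(ann$primary)
  # triplet strictly between the anchors
  expect_true(ann$n_end < ann$triplet_start)
  expect_true(ann$triplet_end < ann$c_start)
})

test_that("records without anchors yield an empty annotation table", {
  ann <- find_kinase_domain(protein_records("pA", strrep("A", 60)))
  expect_equal(nrow(ann), 0L)
})

test_that("two planted domains are both reported, in sequence order", {
  one <- plant_domain(pre = "MA", loop = strrep("L", 8), triplet = "TGY",
                      spacer = "KLMNPA", post = "GG")
  two <- plant_domain(pre = "", loop = strrep("K", 12), triplet = "TNY",
                      spacer = "QRSTVA", post = "DD")
  rec <- protein_records("p2", paste0(one, two))
  ann <- find_kinase_domain(rec)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$triplet, c("TGY", "TNY"))
  expect_true(all(diff(ann$n_start) > 0))
  expect_equal(sum(ann$primary), 1L)
})

test_that("extract_activation_motif applies the selection rule", {
  cat <- anchor_catalog()
  # unique candidate
  seq <- paste0("HRDLKPN", "AQTEYVADSKLMNP", "TRWYRAP")
  got <- extract_activation_motif(seq, c(1L, 7L), c(22L, 28L), cat)
  expect_equal(got$triplet, "TEY")
  # two candidates: KGY sits nearer the C anchor, inside the window
  seq2 <- paste0("HRDLKPN", "TNYAAAAKGYAAAAAA", "TRWYRAP")
  got2 <- extract_activation_motif(seq2, c(1L, 7L), c(24L, 30L), cat)
  expect_equal(got2$triplet, "KGY")
  # no candidate at all
  expect_null(extract_activation_motif(paste0("HRDLKPN", "AAAA", "TRWYRAP"),
                                       c(1L, 7L), c(12L, 18L), cat))
  # region shorter than a triplet
  expect_null(extract_activation_motif(paste0("HRDLKPN", "AA", "TRWYRAP"),
                                       c(1L, 7L), c(10L, 16L), cat))
})

test_that("out-of-window candidates fall back to the nearest one", {
  cat <- anchor_catalog(offset_window = c(4L, 6L))
  # single TEY with a gap of 10 (outside the window) is still chosen
  seq <- paste0("HRDLKPN", "ATEY", strrep("A", 10), "TRWYRAP")
  got <- extract_activation_motif(seq, c(1L, 7L), c(22L, 28L), cat)
  expect_equal(got$triplet, "TEY")
})

test_that("scan_proteins classifies triplets and names genes", {
  co <- gen_kinase_cohort(seed = 5)
  ann <- scan_proteins(co$records)
  expect_equal(nrow(ann), nrow(co$truth))
  expect_true(all(substr(ann$triplet, 3, 3) == "Y"))
  # annotations never overlap the anchors
  expect_true(all(ann$triplet_start > ann$n_end &
                  ann$triplet_end < ann$c_start))
  sc <- ann[ann$genus == "Saccharomyces", ]
  expect_equal(sort(sc$gene_name), paste0("ScMPK-", LETTERS[1:4]))
  expect_true(all(ann$motif_class %in% c("canonical", "novel")))
})

test_that("the packaged anchor config reproduces the default catalog", {
  path <- system.file("extdata", "anchor_catalog.txt", package = "mapkloop")
  cat_file <- read_anchor_catalog(path)
  cat_def <- anchor_catalog()
  expect_equal(format_prosite(cat_file$n_anchor), format_prosite(cat_def$n_anchor))
  expect_equal(format_prosite(cat_file$c_anchor), format_prosite(cat_def$c_anchor))
  expect_equal(cat_file$max_mismatches, cat_def$max_mismatches)
  expect_equal(cat_file$first_residues, cat_def$first_residues)
  expect_equal(cat_file$offset_window, cat_def$offset_window)
})
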