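test_that("position labels parse and order correctly", {
  p <- parse_position_label(c("-1", "1", "27", "27a", "28"))
  expect_equal(p$number, c(-1L, 1L, 27L, 27L, 28L))
  expect_equal(p$suffix, c("", "", "", "a", ""))
  key <- position_key(c("28", "-1", "27a", "1", "27"))
  expect_equal(order(key), c(2, 4, 5, 3, 1))   # -1 < 1 < 27 < 27a < 28
  expect_error(parse_position_label("12ab"), "malformed")
})

test_that("record construction validates symbols, labels and termini", {
  rec <- toy_trna(c("G", "A", "U", "Y", "G"))
  expect_s3_class(rec, "mm_trna")
  expect_equal(rec$five_prime, "phosphate")
  expect_equal(rec$three_prime, "hydroxyl")
  expect_error(toy_trna(c("G", "xyz")), "xyz")
  expect_error(toy_trna(c("G", "A"), labels = c("2", "1")),
               "strictly increasing")
})

test_that("annotated FASTA + sidecar TSV round-trips records exactly", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  rec <- new_trna("demo", c("G", "A", "U", "Y", "m2G", "C"),
                  alleles = list(NULL, c("G"), NULL, NULL, NULL, NULL),
                  partial = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  write_annotated_fasta(rec, fa, tsv)
  back <- read_annotated_fasta(fa, tsv)[["demo"]]
  expect_equal(trna_residues(back), trna_residues(rec))
  expect_equal(back$five_prime, rec$five_prime)
})

test_that("tRNA-His style -1 extension is representable", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">His", "GGCA"), fa)
  writeLines(c("record_id\tindex\tlabel\tsymbol\talleles\tpartial",
               "His\t1\t-1\t\t\t", "His\t2\t1\t\t\t",
               "His\t3\t2\t\t\t", "His\t4\t3\t\t\t"), tsv)
  his <- read_annotated_fasta(fa, tsv)[["His"]]
  res <- trna_residues(his)
  expect_equal(res$label[1], "-1")
  expect_equal(res$symbol[1], "G")
  expect_equal(res$number[1], -1L)
})

test_that("heteroplasmic sites expand by Cartesian enumeration", {
  # one biallelic site, reference first
  asp_like <- new_trna("Asp", c("G", "A", "U"),
                       alleles = list(NULL, "G", NULL))
  ex <- expand_alleles(asp_like)
  expect_length(ex, 2)
  expect_equal(trna_residues(ex[[1]])$symbol, c("G", "A", "U"))
  expect_equal(trna_residues(ex[[2]])$symbol, c("G", "G", "U"))
  expect_equal(attr(ex[[2]], "allele_id"), "2G")
  # two biallelic sites -> 4 records
  two <- new_trna("x", c("A", "C", "U"),
                  alleles = list("G", NULL, "C"))
  expect_length(expand_alleles(two), 4)
  # no alleles -> singleton
  expect_length(expand_alleles(toy_trna(c("G", "A"))), 1)
})

test_that("the shipped catalog reproduces the reference per-row structure", {
  cat22 <- mt_catalog()
  # 14 tRNAs carry m1A at position 9
  expect_equal(sum(cat22$position == "9" & cat22$symbol == "m1A"), 14)
  # the tRNA-Ala entries
  ala <- cat22[cat22$trna == "Ala", ]
  expect_setequal(paste0(ala$symbol, ala$position),
                  c("m1A9", "m2G10", "m2G26", "Y28", "Y39", "Y57"))
  # inserted positions are unique to Ser(UCN)
  ins <- cat22[grepl("[a-z]$", cat22$position), ]
  expect_true(all(ins$trna == "Ser(UCN)"))
  # no 2'-O-methylated species anywhere
  expect_false(any(grepl("^[ACGU]m$", cat22$symbol)))
})

test_that("fixture anticodon wobble bases agree between tables", {
  ac <- mt_anticodons()
  cat22 <- mt_catalog()
  expect_equal(nrow(ac), 22)
  expect_setequal(ac$trna, MT_TRNA_NAMES)
  for (i in seq_len(nrow(ac))) {
    at34 <- cat22$symbol[cat22$position == "34" & cat22$trna == ac$trna[i]]
    if (length(at34)) {
      expect_true(ac$a34[i] %in% at34,
                  label = paste(ac$trna[i], "wobble", ac$a34[i]))
    } else {
      expect_true(ac$a34[i] %in% c("A", "G", "C", "U"))
    }
  }
})

test_that("tRNA-Ala fixture matches its worked-example anchors", {
  ala <- trna_ala()
  res <- trna_residues(ala)
  expect_equal(nrow(res), 72)
  expect_equal(paste0(res$symbol[1:6], collapse = ""), "GAGGAU")
  expect_equal(trna_anticodon(ala), c("U", "G", "C"))
  expect_equal(res$symbol[c(9, 10, 26)], c("m1A", "m2G", "m2G"))
  expect_equal(res$symbol[c(28, 39, 57)], rep("Y", 3))
  expect_true(res$partial[10])   # m2G10 is sub-stoichiometric
  parents <- table(vapply(res$symbol, function(s) reg_lookup(s)$parent, ""))
  expect_equal(unname(parents[c("U", "C", "A", "G")]), c(27, 9, 20, 16),
               ignore_attr = TRUE)
})
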