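test_that("annotation files parse into per-domain records", {
  f <- write_temp_annotations(c(
    "# comment line",
    "hs\tP1\t84-140\t48726",
    "hs\tP1\t270-520\t56112",
    "hs\tP2\t10-85\t57667"
  ))
  rec <- parse_annotations(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(length(unique(rec$protein_id)), 2L)
  expect_equal(rec$region_start[3], 10L)
  expect_equal(rec$region_end[3], 85L)

  # malformed lines are skipped with a warning, or fatal in strict mode
  g <- write_temp_annotations(c("hs\tP1\t84-140\t48726",
                                "hs\tP2\tnot-a-region\t57667"))
  expect_warning(rec2 <- parse_annotations(g), "malformed")
  expect_equal(nrow(rec2), 1L)
  expect_equal(attr(rec2, "skipped")$line, 2L)
  expect_error(parse_annotations(g, strict = TRUE), "line 2")

  empty <- write_temp_annotations("# nothing here")
  expect_warning(rec3 <- parse_annotations(empty), "no annotation records")
  expect_equal(nrow(rec3), 0L)
})

test_that("alternative column layouts are supported via the dialect", {
  f <- write_temp_annotations("P9\t100\t200\t48726\ths")
  d <- annotation_dialect(genome_id = 5, protein_id = 1, region = NA,
                          region_start = 2, region_end = 3,
                          superfamily_id = 4)
  rec <- parse_annotations(f, dialect = d)
  expect_equal(rec$protein_id, "P9")
  expect_equal(rec$region_start, 100L)
  expect_equal(rec$superfamily_id, "48726")
})

test_that("architectures are assembled in N- to C-terminal order", {
  # SH3 / SH2 / kinase ordering by amino-acid position
  f <- write_temp_annotations(c(
    "hs\tSrc\t84-140\tSH3",
    "hs\tSrc\t270-520\tkinase",
    "hs\tSrc\t148-235\tSH2",
    "hs\tP2\t5-60\tZnF"
  ))
  archs <- assemble_architectures(parse_annotations(f))
  expect_identical(archs[["hs|Src"]], c("SH3", "SH2", "kinase"))
  expect_identical(archs[["hs|P2"]], "ZnF")

  # deterministic tie-break on equal starts: by end, then superfamily id
  g <- write_temp_annotations(c(
    "hs\tP\t10-90\tB",
    "hs\tP\t10-50\tA",
    "hs\tP\t10-50\tC"
  ))
  archs2 <- assemble_architectures(parse_annotations(g))
  expect_identical(archs2[["hs|P"]], c("A", "C", "B"))

  # overlapping regions both kept, ordered by start, overlap counted
  h <- write_temp_annotations(c("hs\tQ\t10-50\tX", "hs\tQ\t40-90\tY"))
  archs3 <- assemble_architectures(parse_annotations(h))
  expect_identical(archs3[["hs|Q"]], c("X", "Y"))
  expect_equal(attr(archs3, "n_overlaps"), 1L)
})

test_that("deduplication is exact, ordered and idempotent", {
  archs <- list(c("A", "B"), c("A", "B"), c("B", "A"), "A")
  u <- unique_architectures(archs)
  expect_equal(length(u), 3L)
  expect_identical(u[[1]], "A")
  expect_identical(unique_architectures(u), u)

  distinct <- list(c("X", "Y"), "Z")
  expect_equal(length(unique_architectures(distinct)), 2L)
})

test_that("n-gram counts include NULL boundaries and conserve totals", {
  ct <- count_ngrams(list(c("A", "B")))
  expect_equal(ct$bigram[null_token(), "A"], 1L)
  expect_equal(ct$bigram["A", "B"], 1L)
  expect_equal(ct$bigram["B", null_token()], 1L)
  expect_equal(sum(ct$bigram), 3L)
  expect_identical(unname(ct$trigram[paste(null_token(), "A", "B")]), 1L)

  ct2 <- count_ngrams(list("A", c("A", "B", "A")))
  expect_equal(unname(ct2$monogram["A"]), 3L)
  expect_equal(unname(ct2$monogram["B"]), 1L)
  # presence mode counts each architecture once per token
  ct2p <- count_ngrams(list("A", c("A", "B", "A")), monogram_mode = "presence")
  expect_equal(unname(ct2p$monogram["A"]), 2L)

  set.seed(4)
  corpus <- unique_architectures(random_corpus(40, c("A", "B", "C")))
  ct3 <- count_ngrams(corpus)
  expect_equal(sum(ct3$bigram), sum(lengths(corpus) + 1L))
  expect_equal(sum(ct3$trigram), sum(lengths(corpus)))
  expect_identical(ct3$bigram[null_token(), null_token()], 0L)

  expect_error(count_ngrams(list()), "non-empty")
})

test_that("the default pseudocount resolves to 1 / N_D", {
  corpus <- list("A", "B", "C", "D")
  m <- build_model(count_ngrams(corpus), k = "default")
  expect_equal(m$k, 0.25)
  expect_error(build_model(count_ngrams(corpus), k = -1), "nonnegative")

  # k = 0 with unseen bigrams leaves exact zeros: flagged non-irreducible
  m0 <- build_model(count_ngrams(list(c("A", "B"))), k = 0)
  expect_identical(conditional_probability(m0, "B", "A"), 0)
  expect_error(run_chain(m0, simulation_config(T = 10)), "irreducible")
})

test_that("DA files and model JSON round-trip exactly", {
  set.seed(9)
  corpus <- unique_architectures(random_corpus(25, c("A", "B", "C", "D")))
  f <- tempfile(fileext = ".da")
  write_da_file(corpus, f)
  back <- read_da_file(f)
  expect_identical(back, corpus)
  expect_identical(count_ngrams(back), count_ngrams(corpus))

  m <- build_model(count_ngrams(corpus), k = "default")
  j <- tempfile(fileext = ".json")
  write_model_json(m, j)
  m2 <- read_model_json(j)
  expect_identical(m2$alphabet, m$alphabet)
  expect_equal(m2$k, m$k)
  expect_equal(m2$prob, m$prob)
  expect_identical(m2$counts$bigram, m$counts$bigram)
  expect_identical(m2$counts$trigram, m$counts$trigram)

  # re-smoothing on load without retraining
  m3 <- read_model_json(j, k = 0.5)
  expect_equal(m3$k, 0.5)
})

test_that("the training pipeline runs end to end from files", {
  f <- write_temp_annotations(c(
    "g1\tP1\t1-50\tA", "g1\tP1\t60-100\tB",
    "g1\tP2\t1-40\tA", "g1\tP2\t50-80\tB",
    "g2\tP3\t10-90\tC"
  ))
  tc <- training_corpus(f)
  expect_s3_class(tc, "training_corpus")
  expect_equal(length(tc$unique_architectures), 2L)  # AB duplicated
  expect_identical(tc$alphabet, c("A", "B", "C"))
  expect_equal(tc$counts$n_unique_das, 2L)
})
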