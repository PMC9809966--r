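test_that("volumetric counting follows the events-per-microlitre formula", {
  expect_equal(volumetricCount(2000, 20, 100), 1e7)
  expect_equal(volumetricCount(1, 1, 1), 1000)
  expect_equal(volumetricCount(0, 5, 100), 0)
  expect_error(volumetricCount(10, 0, 1), "volume")
  expect_error(volumetricCount(10, 5, 0.5), "dilution")
})

counts36 <- function(extra = NULL) {
  set.seed(50)
  members <- c("RI", "BH", "BT", "CA")
  v <- matrix(rpois(36 * 4, 500), 36, 4, dimnames = list(NULL, members))
  if (!is.null(extra)) v <- cbind(v, extra)
  gridSampleTable(v, paste0("V", 1:6), c(12, 25, 37, 49, 61, 67),
                  kind = "counts")
}

test_that("contaminant filtering keeps members and repeat offenders", {
  members <- c("RI", "BH", "BT", "CA")
  once <- integer(36); once[5] <- 12          # single-sample contaminant
  twice <- integer(36); twice[c(3, 20)] <- 7  # seen in two samples
  zeros <- integer(36)                        # absent member stays
  tab <- counts36(cbind(Rogue = once, Pseudomonas = twice))
  v <- tableValues(tab)
  colnames(v)[1] <- "PC"; v[, "PC"] <- 0
  tab <- gridSampleTable(v, paste0("V", 1:6), c(12, 25, 37, 49, 61, 67),
                         kind = "counts")
  filt <- filterContaminants(tab, members = c(members, "PC"))
  kept <- colnames(tableValues(filt))
  expect_false("Rogue" %in% kept)
  expect_true("Pseudomonas" %in% kept)
  expect_true("PC" %in% kept)  # member, despite all-zero counts
  # idempotent
  filt2 <- filterContaminants(filt, members = c(members, "PC"))
  expect_identical(tableValues(filt2), tableValues(filt))
})

test_that("copy-number correction renormalises and is scale invariant", {
  tab <- SampleTable(matrix(c(100, 100), 1,
                            dimnames = list("s1", c("A", "B"))),
                     kind = "counts")
  rel <- correctCopyNumber(tab, c(A = 5, B = 2))
  expect_equal(unname(tableValues(rel)[1, ]), c(2 / 7, 5 / 7))
  # equal copy numbers leave proportions unchanged
  tab2 <- SampleTable(matrix(c(30, 70), 1,
                             dimnames = list("s1", c("A", "B"))),
                      kind = "counts")
  rel2 <- correctCopyNumber(tab2, c(A = 4, B = 4))
  expect_equal(unname(tableValues(rel2)[1, ]), c(0.3, 0.7))
  # single-taxon sample
  tab3 <- SampleTable(matrix(50, 1, dimnames = list("s1", "A")), "counts")
  expect_equal(unname(tableValues(correctCopyNumber(tab3, c(A = 7)))[1, ]),
               1)
  expect_error(correctCopyNumber(tab, c(A = 5)), "B")
  # scale invariance per sample
  set.seed(51)
  for (i in 1:10) {
    cnt <- matrix(rpois(4, 100), 1, dimnames = list("s", letters[1:4]))
    cp <- setNames(sample(1:7, 4, replace = TRUE), letters[1:4])
    r1 <- tableValues(correctCopyNumber(SampleTable(cnt, "counts"), cp))
    r2 <- tableValues(correctCopyNumber(SampleTable(cnt * 13, "counts"),
                                        cp))
    expect_equal(r1, r2)
  }
  # all-zero sample is dropped with a warning, not NaN
  z <- SampleTable(matrix(c(0, 0, 10, 10), 2, byrow = TRUE,
                          dimnames = list(c("s0", "s1"), c("A", "B"))),
                   "counts")
  expect_warning(relz <- correctCopyNumber(z, c(A = 1, B = 1)), "s0")
  expect_equal(rownames(tableValues(relz)), "s1")
  expect_false(anyNA(tableValues(relz)))
})

test_that("absolute abundances conserve the total cell counts", {
  rel <- SampleTable(matrix(c(0.25, 0.75, 0.5, 0.5), 2, byrow = TRUE,
                            dimnames = list(c("s1", "s2"), c("A", "B"))),
                     "relative")
  abs_ <- toAbsolute(rel, c(s1 = 1e6, s2 = 0))
  expect_equal(unname(tableValues(abs_)["s1", ]), c(2.5e5, 7.5e5))
  expect_equal(unname(tableValues(abs_)["s2", ]), c(0, 0))
  expect_equal(unname(rowSums(tableValues(abs_))), c(1e6, 0))
  expect_error(toAbsolute(rel, c(s1 = 1e6)), "s2")
  set.seed(52)
  m <- matrix(runif(20), 5, 4)
  m <- m / rowSums(m)
  dimnames(m) <- list(paste0("s", 1:5), letters[1:4])
  tot <- setNames(runif(5, 1e5, 1e9), rownames(m))
  out <- toAbsolute(SampleTable(m, "relative"), tot)
  expect_equal(rowSums(tableValues(out)), tot, tolerance = 1e-12)
})

test_that("classified counts convert to the two relative variants", {
  cc <- new("ClassifiedCounts", counts = c(A = 70, B = 20), unknown = 10,
            labels = character(0), meta = list(sample_id = "s"))
  ab <- classifiedToAbundance(cc, total_cells_per_ml = 1e6)
  expect_equal(unname(ab$rel_with_unknown), c(0.7, 0.2, 0.1))
  expect_equal(unname(ab$rel_without_unknown), c(7 / 9, 2 / 9))
  expect_equal(unname(ab$abs_with_unknown), c(7e5, 2e5, 1e5))
  expect_true(is.na(ab$missing_reason))
  # all unknown: flagged, no renormalised variant
  cc2 <- new("ClassifiedCounts", counts = c(A = 0, B = 0), unknown = 100,
             labels = character(0), meta = list())
  ab2 <- classifiedToAbundance(cc2)
  expect_null(ab2$rel_without_unknown)
  expect_match(ab2$missing_reason, "unknown")
  # zero gated events: missing sample
  cc3 <- new("ClassifiedCounts", counts = c(A = 0), unknown = 0,
             labels = character(0), meta = list())
  expect_match(classifiedToAbundance(cc3)$missing_reason, "zero")
})

test_that("shipped synthetic copy-number table loads", {
  path <- system.file("extdata", "copy_numbers_synthetic.tsv",
                      package = "gutvar")
  cn <- readCopyNumbers(path)
  expect_true(all(c("RI", "BH", "BT", "CA", "PC") %in% names(cn)))
  expect_true(all(cn > 0))
})
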