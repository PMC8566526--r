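# Curation rules: row filters, potency transformation, interference
# catalog, and DT/ST class assignment.

clean_row <- function(id = "c1", target = "T1", value = 100) {
  data.frame(compound_id = id, smiles = "CCO", target_id = target,
             standard_type = "Ki", standard_relation = "=",
             standard_value_nM = value, activity_flag = "",
             target_confidence = 9L, relationship_type = "D",
             organism = "Homo sapiens", mw = 46, stringsAsFactors = FALSE)
}

test_that("p-potency is the negative decadic log of molar potency", {
  expect_equal(toPPotency(100), 7.0)
  expect_equal(toPPotency(10000), 5.0)     # the 10 uM threshold
  expect_equal(toPPotency(1), 9.0)
  expect_error(toPPotency(0), "positive")
  expect_error(toPPotency(-5), "positive")
})

test_that("each violation type is dropped and logged", {
  rows <- do.call(rbind, replicate(7, clean_row(), simplify = FALSE))
  rows$compound_id <- paste0("c", 1:7)
  rows$mw[2] <- 1200
  rows$standard_relation[3] <- ">"
  rows$activity_flag[4] <- "inactive"
  rows$standard_value_nM[5] <- 20000
  rows$target_confidence[6] <- 8L
  rows$relationship_type[7] <- "H"
  out <- filterRecords(rows, interference_catalog = NULL)
  expect_equal(out$compound_id, "c1")
  log <- attr(out, "drop_log")
  expect_equal(unname(log[c("mw_ge_1000", "relation_not_exact", "flagged",
                            "potency_below_10uM", "confidence_lt_9",
                            "relationship_not_D")]),
               rep(1L, 6))
})

test_that("filtering is idempotent and the all-clean table passes unchanged", {
  rows <- do.call(rbind, lapply(1:5, function(i)
    clean_row(paste0("c", i), value = 10^stats::runif(1, 0, 3))))
  once <- filterRecords(rows, interference_catalog = NULL)
  expect_equal(nrow(once), 5)
  back <- once
  back$smiles <- "CCO"; back$standard_type <- "Ki"
  back$standard_relation <- "="; back$activity_flag <- ""
  back$target_confidence <- 9L; back$relationship_type <- "D"
  back$organism <- "Homo sapiens"; back$mw <- 46
  back$standard_value_nM <- 10^(9 - back$p_potency)
  twice <- filterRecords(back[, colnames(rows)], interference_catalog = NULL)
  expect_equal(twice$p_potency, once$p_potency, tolerance = 1e-12)
})

test_that("an empty post-filter set returns an empty frame with a full log", {
  rows <- clean_row(); rows$mw <- 1500
  out <- filterRecords(rows, interference_catalog = NULL)
  expect_equal(nrow(out), 0)
  expect_equal(sum(attr(out, "drop_log")), 1)
})

test_that("a missing column raises an error naming it", {
  rows <- clean_row(); rows$organism <- NULL
  expect_error(filterRecords(rows), "organism")
})

test_that("multiple measurements are averaged on the p-potency scale", {
  rows <- rbind(clean_row(value = 100), clean_row(value = 10000))
  out <- filterRecords(rows, interference_catalog = NULL)
  expect_equal(nrow(out), 1)
  expect_equal(out$p_potency, 6.0)          # mean of 7 and 5
  # measurements straddling the 10 uM threshold are flagged before averaging
  straddling <- rbind(clean_row(value = 100), clean_row(value = 20000))
  expect_message(out2 <- filterRecords(straddling, interference_catalog = NULL),
                 "straddle")
  expect_equal(out2$p_potency, mean(c(7, toPPotency(20000))))
  expect_length(attr(out2, "straddle"), 1)
})

test_that("interference catalog flags matching chemotypes only", {
  catalog <- defaultInterferenceCatalog()
  expect_true(nrow(catalog) >= 5)
  hits <- flagInterference(c("O=C1C=CC(=O)C=C1",     # para-quinone
                             "C",                     # methane
                             "O=c1ccc2ccccc2o1"),     # coumarin motif
                           catalog)
  expect_identical(hits, c(TRUE, FALSE, FALSE))
  empty <- flagInterference("O=C1C=CC(=O)C=C1",
                            catalog[integer(0), , drop = FALSE])
  expect_false(empty)
})

test_that("class assignment separates DT, ST and excluded compounds", {
  pair <- c("A", "B")
  rows <- rbind(
    clean_row("dt", "A", 100), clean_row("dt", "B", 600),
    clean_row("st", "A", 100),
    clean_row("ex", "A", 100), clean_row("ex", "B", 20000))
  cur <- filterRecords(rows, interference_catalog = NULL)
  pd <- assignClasses(cur, pair, raw_table = rows)
  cp <- pairCompounds(pd)
  expect_identical(cp$label[cp$id == "dt"], "DT")
  expect_identical(cp$label[cp$id == "st"], "ST")
  expect_identical(cp$target_id[cp$id == "st"], "A")
  # sub-threshold partner activity excludes the compound entirely
  expect_false("ex" %in% cp$id)
  expect_identical(pd@excluded, "ex")
  # partition: every curated compound is DT, ST or excluded
  expect_setequal(c(cp$id, pd@excluded), unique(cur$compound_id))
})

test_that("a pair without DT compounds warns and returns an empty DT set", {
  rows <- clean_row("only_a", "A", 100)
  cur <- filterRecords(rows, interference_catalog = NULL)
  expect_warning(pd <- assignClasses(cur, c("A", "B"), raw_table = rows),
                 "no DT")
  expect_equal(sum(pairCompounds(pd)$label == "DT"), 0)
})

test_that("synthetic class assignment reproduces generator ground truth", {
  lib <- small_library()
  cp <- compoundTable(lib)
  for (pr in c("pair1", "pair2")) {
    pd <- curate_pair(lib, pr)
    truth <- cp[cp$pair_id == pr, ]
    got <- pairCompounds(pd)
    expect_setequal(got$id[got$label == "DT"],
                    truth$id[truth$final_role == "DT"])
    expect_setequal(got$id[got$label == "ST"],
                    truth$id[truth$final_role %in% c("ST_A", "ST_B")])
    expect_setequal(pd@excluded, truth$id[truth$final_role == "excluded"])
  }
})
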