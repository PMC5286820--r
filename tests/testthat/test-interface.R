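test_that("trace tables round-trip through write and read", {
  sim <- simulateTraces(traceSimConfig(n_roots = 2, seed = 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTraceTable(sim$traces, path)
  back <- readTraceTable(path)
  expect_equal(length(back), length(sim$traces))
  expect_equal(tracePoints(back), tracePoints(sim$traces),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.data.frame(traceData(back)),
               as.data.frame(traceData(sim$traces)))
})

test_that("trace reader names its parse errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("trace_id\tecotype\tx_mm", path)
  expect_error(readTraceTable(path), "lacks columns.*angle_gp")
  writeLines(c("trace_id\tecotype\tangle_gp\treplicate\tpoint_index\tx_mm\ty_mm"),
             path)
  expect_error(readTraceTable(path), "no traces")
  writeLines(c("trace_id\tecotype\tangle_gp\treplicate\tpoint_index\tx_mm\ty_mm",
               "r1\tWS\t90\t1\t2\t0\t1", "r1\tWS\t90\t1\t2\t0\t2"),
             path)
  expect_error(readTraceTable(path), "point_index")
})

test_that("expression studies round-trip through matrix + design TSVs", {
  sim <- simulateExpression(exprSimConfig(n_genes = 40, seed = 2))
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionStudy(sim$study, mp, dp)
  back <- readExpressionStudy(mp, dp)
  expect_equal(exprValues(back), exprValues(sim$study), tolerance = 1e-12)
  expect_equal(studyDesign(back), studyDesign(sim$study))
  # mismatched design is rejected with the offending ids
  des <- studyDesign(sim$study)[-1, ]
  dp2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(des, dp2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readExpressionStudy(mp, dp2), "does not match")
  # duplicate gene ids are rejected
  md <- read.delim(mp, check.names = FALSE)
  md$gene_id[2] <- md$gene_id[1]
  mp2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(md, mp2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readExpressionStudy(mp2, dp), "duplicate gene ids")
})

test_that("contrast results round-trip with full numeric fidelity", {
  sim <- simulateExpression(exprSimConfig(n_genes = 60, seed = 4))
  cm <- comparisonMatrix(sim$study)
  cr <- cm@within[["WS_135_vs_90"]]
  path <- withr::local_tempfile(fileext = ".tsv")
  writeContrastResult(cr, path)
  back <- readContrastResult(path)
  expect_identical(contrastId(back), contrastId(cr))
  for (col in c("log2fc", "t", "p", "q"))
    expect_equal(resultTable(back)[[col]], resultTable(cr)[[col]],
                 tolerance = 1e-12)
  expect_identical(resultTable(back)$sig, resultTable(cr)$sig)
  expect_equal(moderationParams(back)$d0, moderationParams(cr)$d0,
               tolerance = 1e-12)
})

test_that("GEO series-matrix files parse into a probe matrix", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    '!Series_title\t"root skewing arrays"',
    '!Sample_title\t"WS_90_1"\t"WS_90_2"',
    '!Sample_geo_accession\t"GSM001"\t"GSM002"',
    "!series_matrix_table_begin",
    "ID_REF\tGSM001\tGSM002",
    "258958_at\t7.25\t7.31",
    "245222_at\t10.12\t9.98",
    "!series_matrix_table_end"), path)
  sm <- readSeriesMatrix(path)
  expect_equal(dim(sm$values), c(2, 2))
  expect_equal(sm$values["258958_at", "GSM001"], 7.25)
  expect_equal(sm$metadata$Sample_title, c("WS_90_1", "WS_90_2"))
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("!Series_title\tnope", bad)
  expect_error(readSeriesMatrix(bad), "no series matrix table")
})

test_that("run configurations validate and round-trip", {
  cfg <- runConfig(fc_cut = 1.5, inherent_span = 2, moderated = FALSE,
                   seed = 99)
  path <- withr::local_tempfile(fileext = ".yml")
  writeRunConfig(cfg, path)
  expect_identical(readRunConfig(path), cfg)
  expect_error(runConfig(p_cut = 0), "positive")
  writeLines("not_a_key: 1", path)
  expect_error(readRunConfig(path), "unknown config keys")
})

test_that("the morpho subcommand writes metrics, summaries and ANOVA tables", {
  dir <- withr::local_tempdir()
  traces_tsv <- file.path(dir, "traces.tsv")
  expect_equal(rootskewCLI(c("simulate-traces", "--n-roots", "6", "--seed",
                             "3", "--out", traces_tsv)), 0L)
  out <- file.path(dir, "morpho")
  expect_equal(rootskewCLI(c("morpho", "--traces", traces_tsv,
                             "--out-dir", out)), 0L)
  met <- read.delim(file.path(out, "metrics.tsv"))
  expect_equal(nrow(met), 36)
  summ <- read.delim(file.path(out, "summary.tsv"))
  expect_equal(sum(summ$metric == "abs_hgi"), 6)  # six design cells
  an <- read.delim(file.path(out, "anova.tsv"))
  expect_true(all(c("length_mm", "abs_hgi", "str", "wd") %in% an$metric))
  # straight traces: STR exactly 1
  cells <- data.frame(ecotype = "WS", angle_gp = 90, length_mm = 20,
                      skew_angle_deg = 10, wave_count = 0)
  straight <- simulateTraces(traceSimConfig(n_roots = 3, noise_sd_mm = 0,
                                            seed = 1, cells = cells))
  st_tsv <- file.path(dir, "straight.tsv")
  writeTraceTable(straight$traces, st_tsv)
  out2 <- file.path(dir, "morpho2")
  expect_equal(rootskewCLI(c("morpho", "--traces", st_tsv, "--out-dir",
                             out2)), 0L)
  met2 <- read.delim(file.path(out2, "metrics.tsv"))
  expect_equal(met2$str, rep(1, 3), tolerance = 1e-9)
  # malformed input: nonzero status, no crash
  empty <- file.path(dir, "empty.tsv")
  file.create(empty)
  expect_equal(suppressMessages(
    rootskewCLI(c("morpho", "--traces", empty, "--out-dir", out2))), 1L)
})

test_that("the de and classify subcommands chain into a candidate report", {
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "matrix.tsv"); dp <- file.path(dir, "design.tsv")
  tp <- file.path(dir, "truth.tsv")
  expect_equal(rootskewCLI(c("simulate-expression", "--n-genes", "400",
                             "--seed", "11", "--out-matrix", mp,
                             "--out-design", dp, "--out-truth", tp)), 0L)
  cdir <- file.path(dir, "contrasts")
  expect_equal(rootskewCLI(c("de", "--matrix", mp, "--design", dp,
                             "--out-dir", cdir)), 0L)
  files <- list.files(cdir)
  expect_length(files, 7)
  expect_true(all(c("WS_135_vs_90.tsv", "Col0_vs_WS_at_90.tsv") %in% files))
  rdir <- file.path(dir, "report")
  expect_equal(rootskewCLI(c("classify", "--contrast-dir", cdir,
                             "--out-dir", rdir)), 0L)
  venn <- jsonlite::read_json(file.path(rdir, "venn.json"))
  truth <- read.delim(tp)
  # planted HPSGC-like genes dominate the recovered HPSGC set
  expect_gte(venn$venn$hpsgc,
             0.95 * sum(truth$class == "HPSGC_LIKE"))
  cats <- read.delim(file.path(rdir, "categories.tsv"))
  expect_equal(nrow(cats), 400)
  # outputs re-read by the package's own readers
  cr <- readContrastResult(file.path(cdir, "WS_45_vs_90.tsv"))
  expect_s4_class(cr, "ContrastResult")
  # missing contrast file is a named error
  file.remove(file.path(cdir, "WS_45_vs_90.tsv"))
  expect_equal(suppressMessages(
    rootskewCLI(c("classify", "--contrast-dir", cdir, "--out-dir", rdir))),
    1L)
})

test_that("cli rejects malformed invocations cleanly", {
  expect_equal(suppressMessages(rootskewCLI(character(0))), 1L)
  expect_equal(suppressMessages(rootskewCLI("frobnicate")), 1L)
  expect_equal(suppressMessages(rootskewCLI(c("morpho", "--traces"))), 1L)
  expect_equal(suppressMessages(rootskewCLI(c("morpho", "bare"))), 1L)
})
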