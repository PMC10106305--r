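test_that("pathways into the six-month outcomes match the generating structure", {
  pag <- published_pag()
  sf <- causal_paths_to(pag, "SF_6M")
  expect_true("SaC_BL -> Mot_BL -> SF_BL -> SF_6M" %in% sf$label)
  # longest-first ordering
  expect_equal(sf$length, sort(sf$length, decreasing = TRUE))

  of <- causal_paths_to(pag, "OF_6M")
  expect_true(all(c("Mot_BL -> OF_BL -> OF_6M", "SF_6M -> Mot_6M -> OF_6M")
                  %in% of$label))

  # an exogenous node has no incoming causal paths
  expect_equal(nrow(causal_paths_to(pag, "NegSx_BL")), 0)
  expect_error(causal_paths_to(pag, "nope"), class = "causalpaths_unknown_node")
})

test_that("a circle mark on any edge removes paths through it", {
  pag <- published_pag()
  with_circle <- add_edge(pag, "Mot_BL", "SF_BL", "o->")
  sf <- causal_paths_to(with_circle, "SF_6M")
  expect_false(any(grepl("Mot_BL -> SF_BL", sf$label)))
  # but it reappears in the possible-causal list
  sf_poss <- causal_paths_to(with_circle, "SF_6M", include_possible = TRUE)
  expect_true("SaC_BL -> Mot_BL -> SF_BL -> SF_6M" %in%
                sf_poss$label[sf_poss$status == "possible"])
})

test_that("rolled cycles require both the baseline and the follow-up edge", {
  pag <- published_pag()
  pairs <- data.frame(
    concept = c("SaC", "Mot", "SF", "OF"),
    baseline = c("SaC_BL", "Mot_BL", "SF_BL", "OF_BL"),
    followup = c("SaC_6M", "Mot_6M", "SF_6M", "OF_6M"))
  cyc <- rolled_graph(pag, pairs)
  expect_setequal(paste(cyc$var_a, cyc$var_b), c("SaC Mot", "Mot SF"))

  # annotate with fitted effect sizes
  spec <- build_published_model(n = 20000, seed = 81)
  d <- simulate(spec)
  fit <- fit_sem(sem_spec(names(d), paths = spec$edges[, 1:2]), d, baseline = FALSE)
  cyc_es <- rolled_graph(pag, pairs, es = fit)
  sac_mot <- cyc_es[cyc_es$var_a == "SaC", ]
  expect_lt(abs(sac_mot$baseline_es - 0.77), 0.05)
  expect_lt(abs(sac_mot$followup_es - 0.24), 0.05)

  # feed-forward structure only: no cycles
  ff <- mixed_graph(c("A_BL", "B_BL", "A_6M", "B_6M"),
                    edges = data.frame(from = c("A_BL", "A_BL", "B_BL"),
                                       to = c("B_BL", "A_6M", "B_6M"),
                                       type = "-->"))
  pairs2 <- data.frame(concept = c("A", "B"), baseline = c("A_BL", "B_BL"),
                       followup = c("A_6M", "B_6M"))
  expect_equal(nrow(rolled_graph(ff, pairs2)), 0)
})

test_that("edge lists round-trip losslessly", {
  g <- mixed_graph(c("X", "Y", "Z", "W"),
                   edges = data.frame(from = c("X", "Y", "Z"),
                                      to = c("Y", "Z", "X"),
                                      type = c("o->", "<->", "o-o")))
  path <- withr::local_tempfile(fileext = ".txt")
  write_graph(g, path)
  expect_identical(read_graph(path)$M, g$M)

  # empty graph: node declaration, zero edge lines
  e <- mixed_graph(c("A", "B", "C"))
  write_graph(e, path)
  lines <- readLines(path)
  expect_equal(length(lines), 1)
  expect_identical(read_graph(path)$M, e$M)
})

test_that("malformed edge lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("nodes: X Y", "X ?-> Y"), path)
  expect_error(read_graph(path), "line 2", class = "causalpaths_parse_error")
  writeLines(c("X --> Y"), path)
  expect_error(read_graph(path), class = "causalpaths_parse_error")
})

test_that("graphml and dot exports carry endpoint marks", {
  g <- mixed_graph(c("A", "B"), edges = data.frame(from = "A", to = "B", type = "o->"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  dot <- withr::local_tempfile(fileext = ".gv")
  write_graph(g, gml, format = "graphml")
  write_graph(g, dot, format = "dot")
  expect_true(any(grepl("end_from\">circle", readLines(gml))))
  expect_true(any(grepl("arrowtail=odot", readLines(dot))))
})

test_that("the pipeline runs end to end and is byte-reproducible", {
  cfg <- list(
    simulation = list(published_model = TRUE, n = 2000, seed = 5),
    outcomes = list("SF_6M"),
    pairs = list(list(concept = "Mot", baseline = "Mot_BL", followup = "Mot_6M"),
                 list(concept = "SF", baseline = "SF_BL", followup = "SF_6M")),
    stability = list(mode = "jackknife", reps = 3, frac = 0.9),
    seed = 5)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  res <- run_pipeline(cfg, dir1)
  expect_true(all(c("pag.txt", "cpdag.txt", "sem.csv", "fit.json",
                    "stability.csv", "manifest.json") %in% list.files(dir1)))
  expect_s3_class(res$pag, "pag")
  run_pipeline(cfg, dir2)
  for (f in c("pag.txt", "sem.csv", "stability.csv")) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
})

test_that("a missing input file aborts with its name", {
  expect_error(run_pipeline(list(input = "/no/such/file.csv"), withr::local_tempdir()),
               "file.csv", class = "causalpaths_missing_file")
  expect_error(run_pipeline("/no/such/config.yaml", withr::local_tempdir()),
               "config.yaml", class = "causalpaths_missing_file")
})
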