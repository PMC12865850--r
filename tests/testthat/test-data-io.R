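writeTmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("synergy tables parse with normalization and canonical pairs", {
  f <- writeTmp(c("drug_a,drug_b,cell_line,bliss",
                  "Abc ,xyz,CL1,1.5",
                  "XYZ,abc,CL2,-0.25",
                  "Foo-Bar,baz,CL1,0"))
  tab <- loadSynergyTable(f, "synthetic")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$pair_key[1], tab$pair_key[2])  # (B,A) == (A,B)
  expect_true(all(tab$drug_a <= tab$drug_b))
  expect_equal(tab$drug_a[3], "baz")
  expect_equal(tab$drug_b[3], "foobar")
  expect_true(all(!is.na(tab$bliss)))
  expect_true(all(is.na(tab$zip)))  # absent column -> absent, not zero
})

test_that("blank and unparseable score cells become absent with a warning", {
  f <- writeTmp(c("drug_a,drug_b,cell_line,bliss,zip",
                  "a,b,CL1,1.0,",
                  "a,c,CL1,2.0,0.5",
                  "b,c,CL1,3.0,oops"))
  expect_warning(tab <- loadSynergyTable(f, "synthetic"), "unparseable")
  expect_true(is.na(tab$zip[tab$pair_key == pairKey("a", "b")]))
  expect_true(is.na(tab$zip[tab$pair_key == pairKey("b", "c")]))
  expect_equal(tab$bliss, c(1, 2, 3))
})

test_that("missing mandatory synergy columns are named in the error", {
  f <- writeTmp(c("drug_a,drug_b,bliss", "a,b,1"))
  expect_error(loadSynergyTable(f, "synthetic"), "cell_line")
  f2 <- writeTmp(c("drug_a,drug_b,cell_line", "a,b,CL1"))
  expect_error(loadSynergyTable(f2, "synthetic"), "score")
})

test_that("drugcomb dialect maps its column names", {
  f <- writeTmp(c("drug_row,drug_col,cell_line_name,synergy_bliss,S_sum",
                  "A,B,MCF7,2.5,10"))
  tab <- loadSynergyTable(f, "drugcomb")
  expect_equal(tab$bliss, 2.5)
  expect_equal(tab$s_sum, 10)
  expect_equal(tab$cell_line, "MCF7")
})

test_that("numeric severity levels map 0/1/2 to Minor/Moderate/Major", {
  f <- writeTmp(c("drug1,drug2,level", "a,b,2", "a,c,0", "b,c,1"))
  tox <- loadToxicityTable(f, "drugbank")
  lv <- setNames(as.character(tox$level), tox$pair_key)
  expect_equal(unname(lv[pairKey("a", "b")]), "Major")
  expect_equal(unname(lv[pairKey("a", "c")]), "Minor")
  expect_equal(unname(lv[pairKey("b", "c")]), "Moderate")
  expect_true(is.ordered(tox$level))
})

test_that("word severities map directly and unknown tokens are dropped", {
  f <- writeTmp(c("drug1,drug2,severity", "a,b,Moderate", "a,c,Unknown",
                  "b,c,Major"))
  expect_warning(tox <- loadToxicityTable(f, "ddinter"), "unrecognized")
  expect_equal(nrow(tox), 2)
  expect_equal(attr(tox, "log")$n_dropped_unknown, 1)
  f2 <- writeTmp(c("drug1,drug2,severity", "a,b,Unknown"))
  expect_error(suppressWarnings(loadToxicityTable(f2, "ddinter")), "empty")
})

test_that("conflicting duplicate severities resolve to the maximum", {
  f <- writeTmp(c("drug1,drug2,level", "a,b,0", "b,a,2", "a,c,1", "c,a,1"))
  tox <- loadToxicityTable(f, "drugbank")
  expect_equal(nrow(tox), 2)
  expect_equal(as.character(tox$level[tox$pair_key == pairKey("a", "b")]),
               "Major")
  expect_equal(attr(tox, "log")$n_conflicts, 1)  # a/c agrees, a/b conflicts
})

test_that("target tables aggregate to sets; duplicates and isoforms collapse", {
  f <- writeTmp(c("drug,protein", "d1,P1", "d1,P2", "d2,P1", "d1,P1",
                  "d3,P9-2"))
  tg <- loadTargets(f)
  expect_equal(tg$d1, c("P1", "P2"))
  expect_equal(tg$d2, "P1")
  expect_equal(tg$d3, "P9")
  fEmpty <- writeTmp("drug,protein")
  expect_equal(length(loadTargets(fEmpty)), 0)
})

test_that("pathway loading respects views, species and superset invariant", {
  low <- writeTmp(c("P1\tp3\tHomo sapiens",
                    "P2\tp9\tMus musculus"), ext = ".tsv")
  all <- writeTmp(c("P1\tp1\tHomo sapiens",
                    "P1\tp2\tHomo sapiens",
                    "P1\tp3\tHomo sapiens"), ext = ".tsv")
  h <- loadPathways(low, all)
  expect_equal(pathwaySets("P1", h, "lowest"), "p3")
  expect_equal(pathwaySets("P1", h, "all"), c("p1", "p2", "p3"))
  expect_equal(pathwaySets("P2", h, "lowest"), character())  # wrong species
  expect_equal(pathwaySets("P404", h, "all"), character())   # absent protein
})

test_that("a lowest-level pathway missing from the all view is unioned in", {
  low <- writeTmp(c("P1\tp3\tHomo sapiens", "P5\tp7\tHomo sapiens"),
                  ext = ".tsv")
  all <- writeTmp("P1\tp1\tHomo sapiens", ext = ".tsv")
  expect_message(h <- loadPathways(low, all), "union")
  expect_true(all(pathwayView(h, "lowest")$P1 %in% pathwayView(h, "all")$P1))
  expect_equal(pathwayView(h, "all")$P5, "p7")
})

test_that("network loading thresholds edges and dedups", {
  f <- writeTmp(c("protein1 protein2 combined_score",
                  "n1 n2 900", "n2 n3 900", "n3 n1 100", "n2 n1 900"),
                ext = ".txt")
  net <- loadNetwork(f, minEdgeScore = 0)
  expect_equal(igraph::vcount(interactionGraph(net)), 3)
  expect_equal(igraph::ecount(interactionGraph(net)), 3)  # n2-n1 dup dropped
  net2 <- loadNetwork(f, minEdgeScore = 500)
  expect_equal(igraph::ecount(interactionGraph(net2)), 2)
})

test_that("node/edge counts match an independent line-count oracle", {
  set.seed(71)
  n <- 20
  a <- sample(paste0("n", 1:n), 60, replace = TRUE)
  b <- sample(paste0("n", 1:n), 60, replace = TRUE)
  keep <- a != b
  lines <- paste(a[keep], b[keep], 900)
  f <- writeTmp(c("protein1 protein2 combined_score", lines), ext = ".txt")
  net <- loadNetwork(f)
  # oracle: dedup unordered pairs by string key, count distinct endpoints
  key <- paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  expect_equal(igraph::ecount(interactionGraph(net)), length(unique(key)))
  expect_equal(igraph::vcount(interactionGraph(net)),
               length(unique(c(a[keep], b[keep]))))
})

test_that("id map collisions resolve first-wins with a warning", {
  fe <- writeTmp(c("protein1 protein2 combined_score", "n1 n2 900"),
                 ext = ".txt")
  fm <- writeTmp(c("uniprot\tstring_id", "P1\tn1", "P1\tn2", "P2\tn2"),
                 ext = ".tsv")
  expect_warning(net <- loadNetwork(fe, fm), "colliding")
  expect_equal(unname(idMap(net)["P1"]), "n1")
})

makeToyInputs <- function() {
  syn <- writeTmp(c("drug_a,drug_b,cell_line,bliss",
                    "a,b,CL1,1", "a,c,CL1,2", "a,d,CL1,3", "b,c,CL1,4",
                    "b,d,CL1,5"))
  tox <- writeTmp(c("drug1,drug2,level", "a,b,0", "a,c,1", "b,c,2"))
  list(syn = loadSynergyTable(syn, "synthetic"),
       tox = loadToxicityTable(tox, "drugbank"))
}

test_that("assembly drops unlabeled observations and logs the filter", {
  inp <- makeToyInputs()
  ds <- assembleDataset(inp$syn, list(drugbank = inp$tox))
  expect_equal(nrow(observations(ds)), 3)
  lg <- provenance(ds)$filter_log
  expect_equal(lg$n_input, 5)
  expect_equal(lg$n_retained, 3)
  expect_error(validObject(ds), NA)
})

test_that("a total toxicity map filters nothing; retention is monotone", {
  inp <- makeToyInputs()
  total <- writeTmp(c("drug1,drug2,level", "a,b,0", "a,c,1", "a,d,2",
                      "b,c,2", "b,d,1"))
  ds <- assembleDataset(inp$syn, list(drugbank = loadToxicityTable(total)))
  expect_equal(nrow(observations(ds)), nrow(inp$syn))
  dsPart <- assembleDataset(inp$syn, list(drugbank = inp$tox))
  expect_lte(nrow(observations(dsPart)), nrow(inp$syn))
})

test_that("an observation is kept if either of two sources labels it", {
  inp <- makeToyInputs()
  dd <- writeTmp(c("drug1,drug2,severity", "a,d,Major", "b,d,Minor"))
  ds <- assembleDataset(inp$syn,
                        list(drugbank = inp$tox,
                             ddinter = loadToxicityTable(dd, "ddinter")))
  expect_equal(nrow(observations(ds)), 5)
  obs <- observations(ds)
  expect_true(all(is.na(obs$tox_drugbank[obs$drug_b == "d"])))
  expect_equal(sum(!is.na(obs$tox_ddinter)), 2)
})

test_that("assembling with swapped pair order yields the same dataset", {
  inp <- makeToyInputs()
  toxSwapped <- writeTmp(c("drug1,drug2,level", "b,a,0", "c,a,1", "c,b,2"))
  ds1 <- assembleDataset(inp$syn, list(drugbank = inp$tox))
  ds2 <- assembleDataset(inp$syn,
                         list(drugbank = loadToxicityTable(toxSwapped)))
  expect_equal(observations(ds1), observations(ds2))
})

test_that("an empty join is a hard error", {
  inp <- makeToyInputs()
  none <- writeTmp(c("drug1,drug2,level", "x,y,2"))
  expect_error(assembleDataset(inp$syn, list(drugbank = loadToxicityTable(none))),
               "no observations")
})

test_that("collapse-pairs averages scores over cell lines", {
  syn <- writeTmp(c("drug_a,drug_b,cell_line,bliss",
                    "a,b,CL1,1", "a,b,CL2,3", "a,c,CL1,2"))
  tox <- writeTmp(c("drug1,drug2,level", "a,b,1", "a,c,1"))
  ds <- assembleDataset(loadSynergyTable(syn, "synthetic"),
                        list(drugbank = loadToxicityTable(tox)),
                        collapsePairs = "mean")
  obs <- observations(ds)
  expect_equal(nrow(obs), 2)
  expect_equal(obs$bliss[obs$pair_key == pairKey("a", "b")], 2)
})

test_that("dataset export round-trips", {
  inp <- makeToyInputs()
  tg <- list(a = c("P1", "P2"), b = "P1")
  ds <- assembleDataset(inp$syn, list(drugbank = inp$tox), targets = tg,
                        drugTable = data.frame(name = c("a", "b"),
                                               smiles = c("CCO", "Cc1ccccc1")))
  d <- tempfile()
  writeDataset(ds, d)
  back <- readDataset(d)
  expect_equal(observations(back), observations(ds))
  expect_equal(drugs(back)$smiles, drugs(ds)$smiles)
  expect_equal(drugs(back)$targets, drugs(ds)$targets)
})
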