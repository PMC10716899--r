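ala15 <- make_alanine_chain(n_res = 15, n_frames = 5, seed = 1)

test_that("parser builds the documented node shapes", {
  p <- parse_script("s1 = element('H') and protein")
  expect_length(p$diagnostics, 0L)
  st <- p$statements[[1L]]
  expect_equal(st$type, "assign")
  expect_equal(st$name, "s1")
  expect_equal(st$value$type, "and")
  expect_equal(st$value$lhs$name, "element")

  p2 <- parse_script('agly = angle(1,2,3) in resname("GLY")')
  st2 <- p2$statements[[1L]]
  expect_equal(st2$value$type, "in")
  expect_equal(st2$value$lhs$name, "angle")
  expect_equal(st2$value$rhs$name, "resname")

  # errors go through the diagnostics channel, never thrown
  p3 <- parse_script("d1 = distance(")
  expect_gt(length(p3$diagnostics), 0L)
  expect_equal(p3$diagnostics[[1L]]$severity, "error")
  expect_length(p3$statements, 0L)

  # comments, ranges, arithmetic precedence
  p4 <- parse_script("x = 1 + 2 * 3  # trailing comment")
  expect_equal(p4$statements[[1L]]$value$op, "+")
  p5 <- parse_script("r = atoms(2..5)")
  arg <- p5$statements[[1L]]$value$args[[1L]]
  expect_equal(c(arg$lo, arg$hi), c(2L, 5L))
})

test_that("pretty-printed trees re-parse to structurally equal trees", {
  scripts <- c(
    "s1 = element('H') and protein",
    'a1 = angle(1, 2, 3) in resname("ALA")',
    "x = (1 + 2) * distance(1, 2) - 3 / 4",
    "s = not water or atoms(1..3, 7)",
    'd = distance(com(resname("ALA")), com(atoms(1)))')
  for (s in scripts) {
    p1 <- parse_script(s)
    expect_length(p1$diagnostics, 0L)
    printed <- format_script(p1)
    p2 <- parse_script(printed)
    expect_length(p2$diagnostics, 0L)
    expect_equal(strip_tree(p2$statements), strip_tree(p1$statements))
  }
})

test_that("static checking assigns contextual lengths and catches bad input", {
  chk <- check_script(parse_script('a1 = angle(1,2,3) in resname("ALA")'),
                      ala15$topology)
  expect_length(chk$diagnostics, 0L)
  expect_equal(chk$statements[[1L]]$vtype$kind, "float")
  expect_equal(chk$statements[[1L]]$vtype$length, 15L)

  bad <- check_script(parse_script('s = resname("XYZ")'), ala15$topology)
  expect_equal(length(bad$diagnostics), 1L)
  expect_match(bad$diagnostics[[1L]]$message, "XYZ.*not present")

  local_bad <- check_script(
    parse_script('a = angle(1,2,99) in resname("ALA")'), ala15$topology)
  expect_match(format_diagnostics(local_bad$diagnostics),
               "local index 99 exceeds context size 10", all = FALSE)

  expect_match(format_diagnostics(check_script(
    parse_script("e = element('Xx')"), ala15$topology)$diagnostics),
    "unknown element", all = FALSE)
  expect_match(format_diagnostics(check_script(
    parse_script("y = zz + 1"), ala15$topology)$diagnostics),
    "unknown identifier", all = FALSE)
  expect_match(format_diagnostics(check_script(
    parse_script("a = 1\na = 2"), ala15$topology)$diagnostics),
    "already declared", all = FALSE)
  expect_match(format_diagnostics(check_script(
    parse_script("m = protein and 3"), ala15$topology)$diagnostics),
    "selection operands", all = FALSE)
})

test_that("in preserves contexts while and flattens (two-chain system)", {
  two <- make_two_chain_protein(n_res = 4, n_frames = 2)
  pt <- evaluate_script(paste(
    "s1 = protein and chain('A')",
    "s2 = chain('A') in protein", sep = "\n"), two)
  v <- attr(pt, "variables")
  s1 <- v$s1$payload
  s2 <- v$s2$payload
  expect_length(s1$contexts, 1L)          # and flattens
  expect_length(s2$contexts, 2L)          # in keeps one context per protein
  expect_equal(selection_atoms(flatten_contexts(s2)), selection_atoms(s1))
  expect_length(s2$contexts[[2L]], 0L)    # chain A absent from protein B
  # static length always equals context count
  chk <- check_script(parse_script("s2 = chain('A') in protein"),
                      two$topology)
  expect_equal(chk$statements[[1L]]$vtype$length, 2L)
})

test_that("evaluation produces per-frame numeric series with declared lengths", {
  # fixed 1.0-Angstrom pair over 5 frames
  top <- topology(atom_labels = c("C1", "C2"), elements = c("C", "C"),
                  residue_ids = c(1L, 1L), residue_names = rep("UNK", 2),
                  chain_ids = rep("A", 2), bonds = rbind(c(0L, 1L)))
  frames <- lapply(1:5, function(f) {
    md_frame(rbind(c(0, 0, 0), c(1, 0, 0)) + f, unit_cell(), time = f - 1)
  })
  pair <- trajectory(top, frames)
  pt <- evaluate_script("d1 = distance(1, 2)", pair)
  expect_equal(pt$entries$d1$kind, "series")
  expect_equal(pt$entries$d1$payload[, 1L], rep(1, 5))
  expect_equal(pt$entries$d1$unit, "angstrom")

  # population over the 15 ALA contexts
  pt2 <- evaluate_script('a1 = angle(1, 2, 3) in resname("ALA")', ala15)
  expect_equal(pt2$entries$a1$kind, "population_series")
  expect_equal(dim(pt2$entries$a1$payload), c(5L, 15L))
  # evaluated length always equals the statically predicted length
  chk <- check_script(parse_script('a1 = angle(1,2,3) in resname("ALA")'),
                      ala15$topology)
  expect_equal(ncol(pt2$entries$a1$payload),
               chk$statements[[1L]]$vtype$length)

  # arithmetic on series
  pt3 <- evaluate_script("d1 = distance(1, 2)\nd2 = d1 * 2 + 1", pair)
  expect_equal(pt3$entries$d2$payload[, 1L], rep(3, 5))

  # and/or as atom-set operations are commutative
  pta <- evaluate_script("s = element('C') and protein", ala15)
  ptb <- evaluate_script("s = protein and element('C')", ala15)
  expect_equal(selection_atoms(attr(pta, "variables")$s$payload),
               selection_atoms(attr(ptb, "variables")$s$payload))
})

test_that("selections promoted only as properties when numeric; variables kept", {
  pt <- evaluate_script("s1 = protein\nd = distance(1, 2)", ala15)
  expect_equal(names(pt$entries), "d")
  expect_true("s1" %in% names(attr(pt, "variables")))
})

test_that("worker partitioning never changes results", {
  wb <- make_water_box(n_waters = 30, box = 15, n_frames = 8, seed = 5)
  script <- 'g = rdf(element("O"), element("O"), 6.0)'
  pt1 <- evaluate_script(script, wb, workers = 1L)
  pt4 <- evaluate_script(script, wb, workers = 4L)
  expect_identical(pt1$entries$g$payload$counts, pt4$entries$g$payload$counts)
  s1 <- evaluate_script('a = angle(1, 2, 3) in water', wb, workers = 1L)
  s4 <- evaluate_script('a = angle(1, 2, 3) in water', wb, workers = 4L)
  expect_identical(s1$entries$a$payload, s4$entries$a$payload)
})

test_that("runtime degeneracies name the frame and context", {
  top <- topology(atom_labels = c("C1", "C2", "C3"), elements = rep("C", 3),
                  residue_ids = rep(1L, 3), residue_names = rep("UNK", 3),
                  chain_ids = rep("A", 3))
  fr <- md_frame(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  bad <- trajectory(top, list(fr))
  expect_error(
    evaluate_script('a = angle(1, 2, 3) in resid(1)', bad),
    "frame 1, context 1")
})

test_that("suggestions cover operations and contextual variants", {
  sugg <- suggest_snippets(0:2, ala15$topology)   # N, H, CA of residue 1
  snips <- vapply(sugg, `[[`, character(1), "snippet")
  cats <- vapply(sugg, `[[`, character(1), "category")
  expect_true("angle(1, 2, 3)" %in% snips)
  expect_true('angle(1, 2, 3) in resname("ALA")' %in% snips)
  expect_true(all(cats %in% c("operation", "selection")))
  # every emitted snippet parses and validates
  for (s in snips) {
    chk <- check_script(parse_script(paste("v =", s)), ala15$topology)
    expect_length(chk$diagnostics, 0L)
  }
  # two atoms in different residues: distance but no contextual variant
  sugg2 <- suggest_snippets(c(0L, 12L), ala15$topology)
  snips2 <- vapply(sugg2, `[[`, character(1), "snippet")
  expect_true(any(grepl("^distance\\(", snips2)))
  expect_false(any(grepl(" in ", snips2)))
  # one atom: selection suggestions only
  sugg1 <- suggest_snippets(5L, ala15$topology)
  expect_true(all(vapply(sugg1, `[[`, character(1), "category") == "selection"))
  expect_length(suggest_snippets(integer(0), ala15$topology), 0L)
})

test_that("visualization payloads carry markers per context", {
  chk <- check_script(parse_script('a = angle(1,2,3) in resname("ALA")'),
                      ala15$topology)
  nd <- chk$statements[[1L]]$value
  pay <- visualization_payload(nd, ala15, frame = 1L)
  expect_length(pay$points, 3L * 15L)
  expect_length(pay$lines, 2L * 15L)
  expect_length(pay$wedges, 15L)
  expect_length(pay$highlight, 3L * 15L)

  sel_nd <- check_script(parse_script("s = protein"),
                         ala15$topology)$statements[[1L]]$value
  pay2 <- visualization_payload(sel_nd, ala15)
  expect_equal(pay2$highlight, 0:(n_atoms(ala15$topology) - 1L))
  expect_length(pay2$points, 0L)

  lit <- check_script(parse_script("x = 42"),
                      ala15$topology)$statements[[1L]]$value
  pay3 <- visualization_payload(lit, ala15)
  expect_length(pay3$highlight, 0L)
  expect_length(pay3$points, 0L)
})

test_that("import feeds tabular series into scripts", {
  traj <- make_alanine_chain(n_res = 3, n_frames = 4, seed = 2)
  dir <- tempfile(); dir.create(dir)
  writeLines(c("t,e,x", "0,1.5,9", "1,1.7,9", "2,1.9,9", "3,2.1,9"),
             file.path(dir, "ext.csv"))
  pt <- evaluate_script('e = import("ext.csv", "e")', traj, base_dir = dir)
  expect_equal(pt$entries$e$payload[, 1L], c(1.5, 1.7, 1.9, 2.1))
  chk <- check_script(parse_script('e = import("missing.csv")'),
                      traj$topology, base_dir = dir)
  expect_gt(length(chk$diagnostics), 0L)
})
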