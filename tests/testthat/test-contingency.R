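test_that("case status is exact PT matching, never substring", {
  s <- toy_store()
  cs <- is_case(s, TGA)
  expect_equal(sum(cs), 3L)
  expect_equal(s$reports$report_id[cs], c("R1", "R2", "R4"))
  expect_equal(sum(is_case(s, "amnesia")), 0L)
  expect_equal(sum(is_case(s, "  Transient   GLOBAL amnesia ")), 3L)
  expect_error(is_case(s, ""), "non-empty")
})

test_that("exposure honours roles: concomitant does not expose by default", {
  s <- toy_store()
  expect_true(is_exposed(s, "drug x")[1])                      # suspect
  expect_true(is_exposed(s, "drug x")[2])                      # interacting
  expect_false(is_exposed(s, "drug y")[5])                     # concomitant only
  expect_true(is_exposed(s, "drug y", roles = pvsignal:::pv_roles)[5])
  g2 <- drug_group("pair", c("drug q", "drug x"))
  expect_true(is_exposed(s, g2)[2])                            # second member, interacting
})

test_that("build_table enumerates the toy store to (2,1,1,2)", {
  s <- toy_store()
  tab <- build_table(s, TGA, "drug x")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 1, 1, 2))
  expect_equal(tab$n, n_total(s))
})

test_that("unexposed drug gives a = b = 0 and all cases in c", {
  s <- toy_store()
  tab <- build_table(s, TGA, "drug never seen")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(0, 0, 3, 3))
})

test_that("a union group counts each report once; all-drugs group leaves only all-concomitant reports unexposed", {
  s <- toy_store()
  all_g <- drug_group("everything", c("drug x", "drug y", "drug z"))
  tab <- build_table(s, TGA, all_g)
  # R5 lists drug y as concomitant only -> the only unexposed report
  expect_equal(tab$c + tab$d, 1)
  # union a <= sum of singleton a over members (reports counted once)
  singles <- vapply(c("drug x", "drug y", "drug z"),
                    function(dr) build_table(s, TGA, dr)$a, 0)
  expect_true(tab$a <= sum(singles))
})

test_that("a + b + c + d = N for arbitrary generated stores and groups", {
  for (seed in 1:4) {
    s <- random_store(120, seed = seed)
    pts <- unique(s$reactions$term)[1:2]
    grps <- list(unique(s$drugs$active_ingredient)[1],
                 drug_group("g", unique(s$drugs$active_ingredient)[1:3]))
    for (pt in pts) for (g in grps) {
      tab <- build_table(s, pt, g)
      expect_equal(tab$a + tab$b + tab$c + tab$d, n_total(s))
    }
  }
})

test_that("case-side exposure is consistent with an independent count", {
  s <- random_store(250, seed = 11)
  pt <- s$reactions$term[1]
  dr <- s$drugs$active_ingredient[1]
  tab <- build_table(s, pt, dr)
  # independent oracle: base-R set intersection on the raw long tables
  case_ids <- unique(s$reactions$report_id[s$reactions$term == pt])
  exp_ids <- unique(s$drugs$report_id[s$drugs$active_ingredient == dr &
                                        s$drugs$role %in% c("suspect", "interacting")])
  expect_equal(tab$a, length(intersect(case_ids, exp_ids)))
  expect_equal(tab$c, length(setdiff(case_ids, exp_ids)))
})

test_that("eligibility threshold is inclusive at min_cases and role-aware", {
  ids <- sprintf("E%02d", 1:24)
  drugs <- data.table(
    report_id = c(ids[1:4], ids[5:7], ids[8:17], ids[18:24]),
    active_ingredient = c(rep("atenolol", 4), rep("bisoprolol", 3),
                          rep("carvedilol", 10), rep("dummy", 7)),
    role = c(rep("suspect", 4), rep("suspect", 3), rep("concomitant", 10),
             rep("suspect", 7)))
  s <- report_store(mk_reports(ids), drugs,
                    data.table(report_id = ids,
                               term = c(rep("tga", 17), rep("other", 7))))
  el <- eligible_drugs(s, "tga", min_cases = 4)
  expect_equal(el$ingredient, "atenolol")      # 4 cases: boundary included
  expect_equal(el$n_cases, 4L)
  # bisoprolol has 3 (< 4); carvedilol concomitant-only in 10 cases: excluded
  el1 <- eligible_drugs(s, "tga", min_cases = 1)
  expect_false("carvedilol" %in% el1$ingredient)
  expect_true("bisoprolol" %in% el1$ingredient)
  # ties broken alphabetically after count desc
  expect_equal(el1$ingredient, el1[order(-n_cases, ingredient), ingredient])
})
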