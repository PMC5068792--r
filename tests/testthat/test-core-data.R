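test_that("sample tables parse from delimited text with validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup\tph\tphylotype",
               "s1\tg1\t6.5\tRhz1",
               "s1\tg1\t6.5\tGlo1",
               "s2\tg1\t6.7\tRhz1",
               "s2\tg1\t6.7\tAca1"), path)
  st <- read_sample_table(path)
  expect_s3_class(st, "sample_table")
  expect_equal(nrow(st), 4)
  expect_equal(nrow(attr(st, "groups")), 1)
  expect_true(all(st$count == 1))  # count column absent -> presence only

  writeLines(c("sample_id\tgroup\tph\tphylotype",
               "s1\tg1\t6.5\tRhz1",
               "s1\tg1\t6.5\tRhz1"), path)
  expect_error(read_sample_table(path), "s1, Rhz1")

  writeLines(c("sample_id\tgroup\tphylotype", "s1\tg1\tRhz1"), path)
  expect_error(read_sample_table(path), "ph")

  writeLines(c("sample_id\tgroup\tph\tphylotype",
               "s1\tg1\tsix\tRhz1"), path)
  expect_error(read_sample_table(path), "line 1")
})

test_that("sample table invariants reject bad records", {
  base <- data.frame(sample_id = "s1", group = "g1", ph = 6.5,
                     phylotype = "Rhz1", count = 1)
  expect_error(sample_table(transform(base, ph = 15)), "pH")
  expect_error(sample_table(transform(base, count = 0)), "count")
  expect_error(sample_table(transform(base, count = 1.5)), "count")
  expect_error(
    sample_table(base, groups = data.frame(group = "other")),
    "absent from group metadata")
})

test_that("pooling counts distinct samples per group and tracks occurrence", {
  st <- toy_sample_table()
  m <- pool_to_matrix(st)
  expect_equal(attr(m, "cell_kind"), "count")
  expect_equal(m["Rhz1", "acid"], 2)   # present in a1 and a2
  expect_equal(m["Rhz1", "neutral"], 1)
  expect_equal(m["Glo1", "neutral"], 0)
  # row occurrence equals the cell sums over all groups, for every row
  expect_equal(unname(attr(m, "row_occurrence")), unname(rowSums(m)))
  # column gradient is the per-group mean over distinct samples
  expect_equal(unname(attr(m, "col_gradient")["acid"]), mean(c(3.5, 3.8)))
  expect_error(pool_to_matrix(st, grouping = c(a1 = "x")), "not covered")
})

test_that("normalization converts counts to percentages preserving zeros", {
  m <- community_matrix(cbind(g1 = c(5, 0), g2 = c(13, 2)), "count",
                        col_gradient = c(6, 4), row_occurrence = c(18, 2))
  sizes <- data.frame(group = c("g1", "g2"), n_samples = c(10, 13))
  r <- normalize_relative_abundance(m, sizes)
  expect_equal(attr(r, "cell_kind"), "relative_abundance_percent")
  expect_equal(unname(r[1, ]), c(50, 100))
  expect_identical(unname(r == 0), unname(m == 0))
  expect_error(normalize_relative_abundance(r, sizes), "count matrix")
  expect_error(
    normalize_relative_abundance(m, data.frame(group = "g1", n_samples = 10)),
    "g2")
})

test_that("presence conversion is idempotent", {
  m <- community_matrix(cbind(a = c(5, 2), b = c(0, 3)), "count")
  p <- to_presence_absence(m)
  expect_equal(unname(unclass(p))[1:2, ], cbind(c(1, 1), c(0, 1)))
  expect_equal(to_presence_absence(p), p)
})

test_that("hypothesis sorts are deterministic permutations", {
  cells <- cbind(A = c(1, 2, 0), B = c(2, 0, 1), C = c(1, 1, 1))
  rownames(cells) <- c("p1", "p2", "p3")
  m <- community_matrix(cells, "count", col_gradient = c(7.2, 3.7, 5.7),
                        row_occurrence = c(4, 3, 2))
  s <- sort_columns_by_gradient(m)
  expect_equal(colnames(s), c("A", "C", "B"))
  expect_equal(unname(attr(s, "col_gradient")), c(7.2, 5.7, 3.7))
  expect_equal(colnames(sort_columns_by_gradient(m, descending = FALSE)),
               c("B", "C", "A"))
  # ties on the gradient: larger marginal total first, then label
  m2 <- community_matrix(cbind(A = c(1, 0), B = c(1, 1), C = c(1, 0)),
                         "presence", col_gradient = c(5, 5, 5),
                         row_occurrence = c(3, 1))
  expect_equal(colnames(sort_columns_by_gradient(m2)), c("B", "A", "C"))

  r <- sort_rows_by_occurrence(m)
  expect_equal(unname(attr(r, "row_occurrence")), c(4, 3, 2))
  # occurrence ties broken by row total, then label
  m3 <- community_matrix(rbind(p1 = c(1, 1), p2 = c(3, 1), p3 = c(1, 0)),
                         "count", row_occurrence = c(2, 2, 1))
  expect_equal(rownames(sort_rows_by_occurrence(m3)), c("p2", "p1", "p3"))
  # sorting permutes: cell multiset unchanged
  expect_equal(sort(as.vector(s)), sort(as.vector(unclass_cells(m))))
  # single-row matrix passes through
  one <- community_matrix(rbind(p1 = c(1, 1)), "presence",
                          row_occurrence = 2)
  expect_equal(rownames(sort_rows_by_occurrence(one)), "p1")
})

test_that("all-zero rows and columns are dropped with a message", {
  cells <- cbind(g1 = c(2, 0, 1), g2 = c(0, 0, 0))
  rownames(cells) <- c("p1", "p2", "p3")
  expect_message(m <- community_matrix(cells, "count"), "p2")
  expect_message(m <- community_matrix(cells, "count"), "g2")
  suppressMessages(m <- community_matrix(cells, "count"))
  expect_equal(dim(m), c(2, 1))
})

test_that("tables and matrices round-trip through their text formats", {
  st <- toy_sample_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_table(st, path)
  st2 <- read_sample_table(path)
  expect_equal(as.data.frame(st), as.data.frame(st2))
  expect_equal(attr(st, "groups"), attr(st2, "groups"))

  m <- suppressMessages(pool_to_matrix(st))
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_community_matrix(m, mp)
  m2 <- read_community_matrix(mp, cell_kind = "count")
  expect_equal(unname(unclass_cells(m2)), unname(unclass_cells(m)))
  expect_equal(attr(m2, "col_gradient"), attr(m, "col_gradient"))
  expect_equal(unname(attr(m2, "row_occurrence")),
               unname(attr(m, "row_occurrence")))

  gj <- withr::local_tempfile(fileext = ".json")
  write_group_metadata(attr(st, "groups"), gj)
  g2 <- read_group_metadata(gj)
  expect_equal(g2$n_samples, attr(st, "groups")$n_samples)
})
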