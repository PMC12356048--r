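test_that("split projection restricts blocks and reports the kind", {
  N <- LETTERS[1:7]
  L <- LETTERS[1:4]
  p <- project_split(c("C", "D", "E"), N, L)
  expect_setequal(p$block, c("C", "D"))  # {C,D,E} n L | L \ {C,D,E} = {C,D}|{A,B}
  expect_identical(p$kind, "internal")
  expect_identical(project_split(c("F", "G"), N, L)$kind, "empty")
  pe <- project_split(c("D", "E"), N, L)
  expect_identical(pe$kind, "external")
  expect_identical(split_label(pe$block, L), "D|A,B,C")
  expect_error(project_split(c("A", "B"), LETTERS[1:5], LETTERS[1:7]), "subset")
})

test_that("TDR projection sums lengths over each edge's preimage", {
  tp <- tdr_project(fixture_t1_extended(), LETTERS[1:4])
  expect_tree_equal(tp, make_tree(c(A = 2, B = 2, C = 1, D = 3),
                                  internal = list(c("A", "B")),
                                  internal_lengths = 5))
  # identity on the full leaf set, commutes through any intermediate subset
  t <- fixture_t1_extended()
  expect_tree_equal(tdr_project(t, t$leaves), t)
  expect_tree_equal(tdr_project(tdr_project(t, LETTERS[1:5]), LETTERS[1:4]),
                    tdr_project(t, LETTERS[1:4]))
})

test_that("projection of an extension-space member recovers the base tree", {
  # choosing s2 = 1 instead of 2 gives internal length 4 = v_T
  t <- make_tree(c(A = 2, B = 2, C = 1, D = 1, E = 0.5, F = 1.7, G = 0.3),
                 internal = list(c("A", "B"), c("C", "D", "E"), c("D", "E"), c("F", "G")),
                 internal_lengths = c(3, 1, 2, 0.9))
  expect_tree_equal(tdr_project(t, LETTERS[1:4]), fixture_t1())
})

test_that("connection clusters enumerate each maximal orthant exactly once", {
  t4 <- make_tree(c(A = 1, B = 1, C = 1, D = 1), list(c("A", "B")), 1)
  cl5 <- connection_cluster(t4, LETTERS[1:5])
  expect_length(cl5, 5L)
  expect_length(unique(vapply(cl5, orthant_key, character(1))), 5L)
  cl7 <- connection_cluster(t4, LETTERS[1:7])
  expect_length(cl7, 315L)
  expect_length(unique(vapply(cl7, orthant_key, character(1))), 315L)
  # every enumerated orthant projects back onto the tree
  for (o in cl7[seq(1, 315, by = 21)]) {
    expect_s3_class(projection_matrix(t4, o), "projection_matrix")
  }
})

test_that("cluster enumeration matches the double-factorial closed form", {
  for (l in 3:5) for (n in l:7) {
    t <- rtree(l, seed = l * 10 + n)
    cl <- connection_cluster(t, sprintf("L%02d", seq_len(n)))
    expect_length(cl, cluster_size(n, l))
    expect_length(unique(vapply(cl, orthant_key, character(1))), cluster_size(n, l))
  }
})

test_that("enumeration covers exactly the orthants whose projection is the tree", {
  # brute-force scan over all binary topologies on 6 leaves
  t <- rtree(4, seed = 9)
  N <- sprintf("L%02d", 1:6)
  all6 <- connection_cluster(make_tree(structure(rep(1, 3), names = N[1:3])), N)
  expect_length(all6, 105L)  # all binary topologies on 6 leaves
  in_cluster <- vapply(all6, function(o) {
    ok <- tryCatch({ projection_matrix(t, o); TRUE }, error = function(e) FALSE)
    ok
  }, logical(1))
  keys_scan <- sort(vapply(all6[in_cluster], orthant_key, character(1)))
  keys_enum <- sort(vapply(connection_cluster(t, N), orthant_key, character(1)))
  expect_identical(keys_scan, keys_enum)
})

test_that("the worked projection matrix is reproduced exactly", {
  M <- projection_matrix(fixture_t1(), fixture_O1())
  dense <- as.matrix(M)
  raw <- "1000000000001000000000001000000000001000001000000001100"
  expected <- do.call(rbind, lapply(0:4, function(i)
    as.integer(strsplit(substr(raw, i * 11 + 1, i * 11 + 11), "")[[1]])))
  expect_identical(unname(dense), expected)
  expect_identical(fixture_t1()$length, c(2, 2, 1, 3, 4))
  incons <- colnames(dense)[!M$consequential]
  expect_setequal(incons, c("E|A,B,C,D,F,G", "F|A,B,C,D,E,G",
                            "G|A,B,C,D,E,F", "F,G|A,B,C,D,E"))
  expect_identical(qr(dense)$rank, 5L)
})

test_that("projection matrix is the identity when L equals N", {
  t <- rtree(6, seed = 4)
  M <- projection_matrix(t, orthant_of(t))
  expect_identical(unname(as.matrix(M)), diag(1L, 9, 9)[,])
  expect_true(all(M$consequential))
})

test_that("projection matrix rejects orthants outside the cluster", {
  t4 <- make_tree(c(A = 1, B = 1, C = 1, D = 1), list(c("A", "B")), 1)
  bad <- make_orthant(LETTERS[1:5], list(c("A", "C"), c("A", "C", "E")))
  expect_error(projection_matrix(t4, bad), "not in the connection cluster")
})

test_that("the worked reduced system is reproduced exactly", {
  sys <- build_reduced_system(fixture_t1(), fixture_O1(), fixture_t2(), fixture_O2())
  expect_identical(sys$v, c(2, 2, 1, 3, 4, 1, 1, 2, 2, 2, 3, 3))
  A <- extspace:::system_matrix(sys)
  n1 <- sum(sys$var_tree == 1L)
  M1r <- apply(A[1:5, 1:n1], 1, paste, collapse = "")
  M2r <- apply(A[6:12, (n1 + 1):sys$nvar], 1, paste, collapse = "")
  expect_identical(unname(M1r),
                   c("1000000", "0100000", "0010000", "0001001", "0000110"))
  expect_identical(unname(M2r),
                   c("100000000", "010000000", "001000000", "000100000",
                     "000010000", "000001000", "000000111"))
  # copy rules: eF, eG and the {F,G} split flow from tree 2; eD from tree 1
  lab <- function(m) split_label(extspace:::labels_of(m, sys$leaves), sys$leaves)
  copies <- vapply(sys$copy_rules, function(cr) paste0(lab(cr$mask), "<", cr$from),
                   character(1))
  expect_setequal(copies, c("D|A,B,C,E,F,G<1", "F|A,B,C,D,E,G<2",
                            "G|A,B,C,D,E,F<2", "F,G|A,B,C,D,E<2"))
  zeros <- vapply(sys$zero_rules, function(zr) lab(zr$mask), character(1))
  expect_identical(zeros, "E|A,B,C,D,F,G")
})

test_that("a degenerate system (L1 = L2 = N) pins the single point", {
  t1 <- rtree(5, seed = 21)
  t2 <- rtree(5, seed = 22)
  sys <- build_reduced_system(t1, orthant_of(t1), t2, orthant_of(t2))
  expect_identical(sys$nvar, sys$nrow)
  expect_length(sys$copy_rules, 0L)
  expect_length(sys$zero_rules, 0L)
  pr <- reconstruct_pair(sys$v, sys)
  expect_tree_equal(pr[[1]], t1)
  expect_tree_equal(pr[[2]], t2)
})

test_that("feasible points reconstruct into the two extension spaces", {
  set.seed(5)
  for (s in 1:6) {
    sys <- random_system(6, 5, 4, seed = s)
    for (rep in 1:3) {
      x <- random_feasible(sys)
      expect_lte(extspace:::feasibility_residual(x, sys), 1e-9)
      pr <- reconstruct_pair(x, sys)
      expect_tree_equal(tdr_project(pr[[1]], sys$t1$leaves), sys$t1, tol = 1e-9)
      expect_tree_equal(tdr_project(pr[[2]], sys$t2$leaves), sys$t2, tol = 1e-9)
      # boundedness: every edge is bounded by the matching base-tree row value
      for (j in seq_len(sys$nvar)) {
        expect_lte(x[j], sys$v[sys$var_row[j]] + 1e-9)
      }
    }
  }
})

test_that("reconstruction applies the worked example's copy and zero rules", {
  sys <- build_reduced_system(fixture_t1(), fixture_O1(), fixture_t2(), fixture_O2())
  x <- c(2, 2, 1, 1, 3, 1, 2,  1, 1, 2, 2, 2, 3, 1, 1, 1)
  pr <- reconstruct_pair(x, sys)
  lab1 <- vapply(pr[[1]]$split, extspace:::split_label_mask, character(1),
                 leaves = pr[[1]]$leaves)
  len1 <- pr[[1]]$length
  expect_equal(len1[lab1 == "D|A,B,C,E,F,G"], 1)  # eD variable
  expect_equal(len1[lab1 == "D,E|A,B,C,F,G"], 2)  # s3 variable, 1 + 2 = v row
  expect_equal(len1[lab1 == "E|A,B,C,D,F,G"], 0)  # zero rule
  expect_equal(len1[lab1 == "F|A,B,C,D,E,G"], 2)  # copied from tree 2
  expect_equal(len1[lab1 == "F,G|A,B,C,D,E"], 1)  # copied from tree 2
  # re-extracting the variables is the identity
  back <- c(pr[[1]]$length[match(sys$var_mask[sys$var_tree == 1L], pr[[1]]$split)],
            pr[[2]]$length[match(sys$var_mask[sys$var_tree == 2L], pr[[2]]$split)])
  expect_equal(back, x)
  expect_error(reconstruct_pair(x + 0.5, sys), "infeasible")
})
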