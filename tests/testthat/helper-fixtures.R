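# Shared fixtures: the worked 7-leaf projection example and its companion
# 5-leaf tree, plus small random-tree helpers.

# T: 4 leaves, internal split {A,B}|{C,D} of length 4
fixture_t1 <- function() {
  make_tree(c(A = 2, B = 2, C = 1, D = 3),
            internal = list(c("A", "B")), internal_lengths = 4)
}

# orthant O of the 7-leaf extension of T, splits s1..s4
fixture_O1 <- function() {
  make_orthant(LETTERS[1:7],
               list(c("A", "B"), c("C", "D", "E"), c("D", "E"), c("F", "G")))
}

# T2: 5 leaves {A,B,C,F,G} with internal splits {A,B} and {F,G}, both 3
fixture_t2 <- function() {
  make_tree(c(A = 1, B = 1, C = 2, F = 2, G = 2),
            internal = list(c("A", "B"), c("F", "G")),
            internal_lengths = c(3, 3))
}

# orthant O2 of the 7-leaf extension of T2
fixture_O2 <- function() {
  make_orthant(LETTERS[1:7],
               list(c("A", "B"), c("A", "B", "C"), c("E", "F", "G"), c("F", "G")))
}

# a 7-leaf tree inside O1 with coordinate vector
# (eA..eG, s1..s4) = (2,2,1,1,0.5,1.7,0.3, 3,2,2,0.9)
fixture_t1_extended <- function() {
  make_tree(c(A = 2, B = 2, C = 1, D = 1, E = 0.5, F = 1.7, G = 0.3),
            internal = list(c("A", "B"), c("C", "D", "E"), c("D", "E"), c("F", "G")),
            internal_lengths = c(3, 2, 2, 0.9))
}

rtree <- function(n_or_leaves, seed, model = length_model("unimodal")) {
  leaves <- if (is.numeric(n_or_leaves)) sprintf("L%02d", seq_len(n_or_leaves))
  else n_or_leaves
  random_binary_tree(leaves, model, seed = seed)
}

expect_tree_equal <- function(a, b, tol = 1e-9) {
  expect_true(tree_equal(a, b, tol = tol))
}

orthant_key <- function(o) paste(sort(o$splits), collapse = ",")

pick1 <- function(v) v[sample.int(length(v), 1L)]
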