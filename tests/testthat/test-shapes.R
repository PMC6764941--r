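test_that("the classifier recognizes the canonical shape examples", {
  expect_identical(classify_pair(cherry_net(), "x", "y")$kind,
                   "LAMBDA_CHERRY")
  expect_identical(classify_pair(lambda3(), "x", "y")$kind, "lambda_xy")
  expect_identical(classify_pair(lambda3(), "y", "x")$kind, "lambda_yx")
  expect_identical(classify_pair(a_shape_net(), "x", "y")$kind, "A_xy")
  expect_identical(classify_pair(a_shape_net(), "y", "x")$kind, "A_yx")
  expect_identical(classify_pair(h_shape_net(), "x", "y")$kind, "H_xy")
  ## the subdivided cherry also holds on {x, c} in the lambda fixture
  expect_identical(classify_pair(lambda3(), "x", "c")$kind, "lambda_xy")
  ## a balanced 4-leaf tree has distance 4 between opposite leaves
  bal <- read_enewick("(((x,y),(z,w)));")
  expect_identical(classify_pair(bal, "x", "z")$kind, "PI")
  expect_error(classify_pair(cherry_net(), "x", "x"), "distinct")
})

test_that("classifier agrees with the motif-matching oracle on random nets", {
  nets <- sample_nets(20, seed = 107, max_leaves = 12)
  seen <- character()
  for (net in nets) {
    for (pr in leaf_pairs(net)) {
      a <- classify_pair(net, pr[1], pr[2])
      b <- oracle_classify_pair(net, pr[1], pr[2])
      expect_identical(a$kind, b$kind)
      seen <- union(seen, c(a$kind, tcnets:::swap_kind(a$kind)))
      ## exactly one shape holds per unordered pair: the swapped query must
      ## be the orientation-swapped kind
      expect_identical(classify_pair(net, pr[2], pr[1])$kind,
                       tcnets:::swap_kind(a$kind))
    }
  }
  ## the codomain has eight values and the generator realizes all of them
  expect_setequal(seen, c("LAMBDA_CHERRY", "lambda_xy", "lambda_yx",
                          "A_xy", "A_yx", "H_xy", "H_yx", "PI"))
})

## true shape of each pair together with the observed MLLS shapes
shape_census <- function(net) {
  mllss <- mlls_set(net)
  k <- network_level(net)
  blobs <- network_blobs(net)
  lapply(leaf_pairs(net), function(pr) {
    true <- classify_pair(net, pr[1], pr[2])
    obs <- vapply(mllss, function(m) classify_pair(m, pr[1], pr[2])$kind,
                  character(1))
    ## blob level of the reticulation, for the K shapes
    lv <- NA_integer_
    if (true$kind %in% c("A_xy", "H_xy", "A_yx", "H_yx")) {
      ret <- if (true$kind %in% c("A_xy", "H_xy"))
        tcnets:::net_parents(net, tcnets:::resolve_leaf(net, pr[2]))
      else tcnets:::net_parents(net, tcnets:::resolve_leaf(net, pr[1]))
      for (b in blobs) if (ret %in% b$members) lv <- b$level
    }
    list(pair = pr, true = true$kind, obs = obs, ret_level = lv, k = k)
  })
}

test_that("shape preservation and exclusion across MLLSs", {
  for (net in sample_nets(6, seed = 109, max_leaves = 12)) {
    for (cs in shape_census(net)) {
      sw <- tcnets:::swap_kind
      ## preservation: the original shape appears in at least one MLLS
      expect_true(cs$true %in% cs$obs)
      ## exclusion rows of the identifiability table
      if (cs$true == "LAMBDA_CHERRY")
        expect_true(all(cs$obs == "LAMBDA_CHERRY"))
      if (cs$true %in% c("A_xy", "A_yx"))
        expect_true(all(cs$obs == cs$true))
      if (cs$true %in% c("lambda_xy", "lambda_yx"))
        expect_true(all(cs$obs %in% c("LAMBDA_CHERRY", cs$true)))
      if (cs$true %in% c("H_xy", "H_yx")) {
        if (cs$ret_level < cs$k) {
          expect_true(all(cs$obs == cs$true))
        } else {
          hx <- if (cs$true == "H_xy") c("A_yx", "H_yx") else c("A_xy", "H_xy")
          expect_false(any(cs$obs %in% hx))        # no opposite K
          expect_true("LAMBDA_CHERRY" %in% cs$obs) # isolation survives
        }
      }
      if (cs$true == "PI")
        expect_false("LAMBDA_CHERRY" %in% cs$obs)  # distance >= 4 exclusion
    }
  }
})

test_that("the original shape is inferred exactly from the MLLS shapes", {
  for (net in sample_nets(6, seed = 113, max_leaves = 12)) {
    mllss <- mlls_set(net)
    k <- network_level(net)
    for (cs in shape_census(net)) {
      inf <- infer_original_shape(
        lapply(mllss, classify_pair, x = cs$pair[1], y = cs$pair[2]))
      expect_identical(inf$shape$kind, cs$true)
      if (cs$true %in% c("H_xy", "H_yx"))
        expect_identical(inf$levelk, cs$ret_level == k)
      else expect_true(is.na(inf$levelk))
    }
  }
})

test_that("inference rejects impossible shape sets", {
  mk <- function(kinds) lapply(kinds, function(k) tcnets:::new_shape(k, "x", "y"))
  ## a cherry in some but not all MLLSs, with nothing else to explain it
  expect_error(infer_original_shape(mk(c("LAMBDA_CHERRY", "lambda_xy",
                                         "lambda_yx"))), "inconsistent")
  ## opposite subdivided cherries cannot coexist
  expect_error(infer_original_shape(mk(c("lambda_xy", "lambda_yx"))),
               "inconsistent")
})
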