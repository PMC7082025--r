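ref_net <- data.frame(source = c("Da", "Dc"), target = c("Db", "Db"))

test_that("homology loading enforces the strict e-value cutoff", {
  hits <- data.frame(query = c("u", "v", "w"), subject = c("Da", "Db", "Dc"),
                     evalue = c(1e-20, 1e-10, 1e-15))
  hom <- load_homology(hits, e_threshold = 1e-15)
  expect_equal(hom$query, "u")            # 1e-10 and the exact boundary drop
  ## 12-column tabular input with a malformed row
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("u", "Da", 99, 100, 1, 0, 1, 100, 1, 100, "1e-30", 200),
                     collapse = "\t"),
               paste(c("v", "Db", 99, 100, 1, 0, 1, 100, 1, 100, "bogus", 200),
                     collapse = "\t")), tmp)
  expect_message(hom2 <- load_homology(tmp), "malformed")
  expect_equal(hom2$query, "u")
})

test_that("edge conservation uses direct or indirect reachability of homologs", {
  hom <- load_homology(data.frame(query = c("u", "v", "x"),
                                  subject = c("Da", "Db", "Dc"),
                                  evalue = 1e-30), 1e-15)
  net <- signed_network(data.frame(source = c("u", "x", "q", "v"),
                                   target = c("v", "v", "v", "u"),
                                   sign = 1L))
  flags <- flag_conserved_edges(net, ref_net, hom)
  names(flags) <- paste(net$edges$source, net$edges$target)
  expect_true(flags[["u v"]])     # direct: Da -> Db
  expect_true(flags[["x v"]])     # direct: Dc -> Db
  expect_false(flags[["q v"]])    # no homolog for q
  expect_false(flags[["v u"]])    # no path Db -> Da
  ## indirect path
  ref2 <- rbind(ref_net, data.frame(source = "Dm", target = "Da"))
  hom2 <- rbind(hom, data.frame(query = "z", subject = "Dm", evalue = 1e-30))
  class(hom2) <- class(hom)
  net2 <- signed_network(data.frame(source = "z", target = "v", sign = 1L))
  expect_true(flag_conserved_edges(net2, ref2, hom2))   # Dm -> Da -> Db
  expect_false(flag_conserved_edges(net2, ref2, hom2, max_path_length = 1))
  ## monotone: adding reference edges never unconserves anything
  ref3 <- rbind(ref2, data.frame(source = "Db", target = "Dc"))
  f2 <- flag_conserved_edges(net, ref2, hom)
  f3 <- flag_conserved_edges(net, ref3, hom)
  expect_true(all(f3 >= f2))
})

## A hand-built scenario: master -> root of an FFL whose three TFs regulate
## modules; one peripheral conserved TF.
contract_fixture <- function() {
  edges <- data.frame(
    source = c("M", "A", "A", "B", "P"),
    target = c("A", "B", "C", "C", "C"),
    sign = 1L)
  net <- signed_network(edges)
  hom <- load_homology(data.frame(query = "P", subject = "Da",
                                  evalue = 1e-30), 1e-15)
  calls <- data.frame(tf = c("M", "A", "B", "C", "P"),
                      module = c("m4", "m1", "m2", "m3", "m1"),
                      called = TRUE, motif_min_p = 0.01,
                      granger_min_bh_p = 0.01)
  cons <- flag_conserved_edges(net, ref_net, hom)
  list(net = net, hom = hom, calls = calls, cons = cons)
}

test_that("contraction retains the most-upstream TF and collapses FFL blocks", {
  fx <- contract_fixture()
  ctr <- contract_network(fx$net, fx$cons, fx$hom, fx$calls, hsf_id = "B")
  ## criterion 1: M has zero in-degree among candidates and is retained
  expect_true("M" %in% ctr$retained$most_upstream)
  ## criterion 2: the A/B/C feed-forward loop collapses into one block
  expect_length(ctr$blocks, 1)
  expect_setequal(ctr$blocks[[1]]$members, c("A", "B", "C"))
  ## conserved/peripheral P is not retained (it has a homolog)
  expect_false("P" %in% ctr$nodes$id)
  ## the unique most-upstream node is the planted master
  expect_equal(most_upstream(ctr), "M")
  ## block membership is disjoint from plain nodes
  expect_length(intersect(ctr$nodes$id[ctr$nodes$type == "tf"],
                          unlist(lapply(ctr$blocks, `[[`, "members"))), 0)
})

test_that("contraction is a deterministic function of its inputs", {
  fx <- contract_fixture()
  ctr1 <- contract_network(fx$net, fx$cons, fx$hom, fx$calls, hsf_id = "B")
  ctr2 <- contract_network(fx$net, fx$cons, fx$hom, fx$calls, hsf_id = "B")
  expect_identical(ctr1$nodes, ctr2$nodes)
  expect_identical(ctr1$edges, ctr2$edges)
  expect_identical(ctr1$blocks, ctr2$blocks)
})

test_that("end-to-end contraction of a planted study truth finds the master", {
  study <- synthetic_study(seed = 1)
  net <- study$data$network
  sn <- signed_network(data.frame(
    source = net$edges$source, target = net$edges$target,
    sign = net$edges$sign, score = 1, conditions = "trehalose",
    lag1_cc = net$edges$sign * 0.9, conflict = FALSE), nodes = net$tf_ids)
  hom <- load_homology(study$homology_hits, 1e-15)
  cons <- flag_conserved_edges(sn, study$reference_network, hom)
  calls <- data.frame(tf = unname(study$module_drivers),
                      module = names(study$module_drivers), called = TRUE,
                      motif_min_p = 0.01, granger_min_bh_p = 0.01)
  ctr <- contract_network(sn, cons, hom, calls, hsf_id = study$hsf_id)
  expect_equal(most_upstream(ctr), net$master_regulator)
})

test_that("an empty candidate set contracts to an empty network with a warning", {
  fx <- contract_fixture()
  no_calls <- within(fx$calls, called <- FALSE)
  expect_warning(ctr <- contract_network(fx$net, fx$cons, fx$hom, no_calls,
                                         hsf_id = "B"), "empty candidate")
  expect_equal(nrow(ctr$nodes), 0)
})
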