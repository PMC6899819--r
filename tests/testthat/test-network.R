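test_that("packaged corticosteroids network matches its printed source", {
  net <- corticosteroids()
  expect_equal(net$n_studies, 18)
  expect_equal(net$n_treatments, 8)
  expect_equal(nrow(net$arms), 36)
  # star network of placebo-controlled trials, 7 distinct designs
  expect_true(is_star(net))
  ds <- summarize_designs(net)
  expect_equal(nrow(ds), 7)
  expect_equal(sum(ds$count), 18)
  expect_true(all(grepl("^1\\+", ds$design)))
  # four placebo arms with zero events; none for mometasone
  expect_equal(count_zero_event_arms(net, 1), 4)
  expect_equal(count_zero_event_arms(net, 7), 0)
  # placebo arm sizes exactly as printed
  placebo <- net$arms[net$arms$treatment == 1, ]
  expect_equal(placebo$size,
               c(38, 43, 51, 30, 54, 16, 12, 33, 11, 12, 10, 78, 33, 30, 17,
                 44, 33, 15))
})

test_that("validation rejects malformed arm tables with informative errors", {
  expect_error(nma_network(data.frame(study = integer(), treatment = integer(),
                                      events = integer(), size = integer())),
               "empty")
  expect_error(two_arm_net(events = c(5, 9, 2, 45)), "exceed")
  expect_error(nma_network(data.frame(study = c(1, 1, 2),
                                      treatment = c(1, 2, 1),
                                      events = c(1, 2, 3),
                                      size = c(10, 10, 10))),
               "at least 2 arms")
  expect_error(nma_network(data.frame(study = c(1, 1, 1),
                                      treatment = c(1, 2, 2),
                                      events = c(1, 2, 3),
                                      size = c(10, 10, 10))),
               "duplicate")
  expect_error(nma_network(data.frame(study = c(1, 1), treatment = c(1, 2),
                                      events = c(0, 1), size = c(0, 10))),
               "size")
})

test_that("treatment relabeling is dense and preserves numeric coding", {
  net <- nma_network(data.frame(study = c(1, 1, 2, 2),
                                treatment = c(2, 7, 2, 5),
                                events = c(1, 2, 3, 4),
                                size = rep(10, 4)),
                     reference = 2)
  expect_equal(net$treatment_labels, c("2", "5", "7"))
  expect_equal(sort(unique(net$arms$treatment)), 1:3)
  expect_equal(net$reference, 1)  # label "2" became id 1
  labeled <- nma_network(data.frame(study = c(1, 1), treatment = c("pbo", "drug"),
                                    events = c(1, 2), size = c(10, 10)),
                         reference = "pbo")
  expect_equal(labeled$treatment_labels, c("drug", "pbo"))
  expect_equal(labeled$reference, 2)
})

test_that("CSV round-trip reproduces the table and the wide reader agrees", {
  net <- corticosteroids()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_network(net, tmp)
  again <- read_network(tmp, reference = 1)
  expect_equal(again$arms, net$arms)
  expect_equal(again$treatment_labels, net$treatment_labels)

  wide <- withr::local_tempfile(fileext = ".csv")
  act <- net$arms[net$arms$treatment != 1, ]
  ref <- net$arms[net$arms$treatment == 1, ]
  utils::write.csv(data.frame(study = act$study,
                              active_treatment = act$treatment,
                              active_events = act$events,
                              active_size = act$size,
                              ref_treatment = ref$treatment,
                              ref_events = ref$events,
                              ref_size = ref$size),
                   wide, row.names = FALSE)
  net_w <- read_network(wide, dialect = "wide", reference = 1)
  expect_equal(net_w$arms, net$arms)
})

test_that("design summaries count every study once on random networks", {
  set.seed(7)
  for (rep in 1:10) {
    ns <- sample(2:12, 1)
    K <- sample(2:5, 1)
    arms <- do.call(rbind, lapply(seq_len(ns), function(i) {
      n_arm <- min(sample(2:3, 1), K)
      trts <- sort(sample(seq_len(K), n_arm))
      data.frame(study = i, treatment = trts,
                 events = rbinom(length(trts), 20, 0.3), size = 20)
    }))
    net <- nma_network(arms)
    expect_equal(sum(summarize_designs(net)$count), net$n_studies)
  }
})

test_that("star detection and zero-event counting behave on edge cases", {
  expect_true(is_star(two_arm_net()))
  non_star <- nma_network(data.frame(study = c(1, 1, 2, 2),
                                     treatment = c(1, 2, 2, 3),
                                     events = c(1, 1, 1, 1),
                                     size = rep(10, 4)))
  expect_false(is_star(non_star))
  expect_error(count_zero_event_arms(two_arm_net(), 9), "not present")
})

test_that("L'Abbe coordinates are the observed per-arm event fractions", {
  net <- corticosteroids()
  pts <- labbe_points(net)
  expect_equal(nrow(pts), 18)
  expect_equal(pts$ref_frac[pts$study == "5"], 21 / 54)
  expect_equal(pts$other_frac[pts$study == "5"], 48 / 61)
  expect_equal(pts$ref_frac[pts$study == "1"], 1 / 38)
  expect_equal(pts$other_frac[pts$study == "1"], 27 / 84)
  zz <- nma_network(data.frame(study = c(1, 1), treatment = c(1, 2),
                               events = c(0, 0), size = c(5, 5)))
  expect_equal(unlist(labbe_points(zz)[, c("ref_frac", "other_frac")]),
               c(ref_frac = 0, other_frac = 0))
  no_ref <- nma_network(data.frame(
    study = c(1, 1, 2, 2), treatment = c(1, 2, 2, 3),
    events = c(1, 1, 1, 1), size = c(9, 9, 9, 9)))
  expect_error(labbe_points(no_ref), "without reference arm: 2")
})
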