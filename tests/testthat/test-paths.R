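test_that("fusion grouping partitions the reference cohort into 8 groups", {
  pts <- reference_fusion_patients()
  g <- assign_fusion_groups(read_fusions(pts))
  expect_identical(nrow(g$table), 8L)
  expect_identical(sum(g$table$n), 67L)
  expect_identical(nrow(g$assignment), 67L)
  # distinct (uiv, liv) pairs map to distinct groups
  expect_identical(anyDuplicated(paste(g$table$uiv, g$table$liv)), 0L)
  # the T2-T12 level holds its 8 patients in a single group
  t2t12 <- g$table$group[g$table$uiv == "T2" & g$table$liv == "T12"]
  expect_identical(sum(g$assignment$group == t2t12), 8L)

  # single-level cohort collapses to one group
  one <- assign_fusion_groups(read_fusions(
    data.frame(patient_id = paste0("q", 1:8), uiv = "T2", liv = "T12")))
  expect_identical(nrow(one$table), 1L)
  expect_identical(one$table$n, 8L)

  # empty input gives an empty table
  empty <- assign_fusion_groups(read_fusions(
    data.frame(patient_id = character(), uiv = character(),
               liv = character())))
  expect_identical(nrow(empty$table), 0L)
})

test_that("small-group filtering removes exactly the undersized groups", {
  g <- assign_fusion_groups(read_fusions(reference_fusion_patients()))
  f <- filter_small_groups(g, 3L)
  expect_identical(length(f$removed_patients), 3L)
  expect_identical(nrow(f$kept$assignment), 64L)
  expect_identical(nrow(f$kept$table), 6L)
  # renumbering is contiguous and order-preserving
  expect_identical(f$kept$table$group, 1:6)
  expect_identical(sum(f$kept$table$n), 64L)
  # the removed patients are exactly those of the undersized levels
  rem <- g$assignment$patient_id[g$assignment$group %in%
                                   g$table$group[g$table$n < 3]]
  expect_setequal(f$removed_patients, rem)

  expect_identical(length(filter_small_groups(g, 1L)$removed_patients), 0L)
  expect_error(filter_small_groups(g, 100L), "smaller than min_n")
})

test_that("treatment paths are pure functions of the (PO, EP, F) triple", {
  fus <- read_fusions(data.frame(patient_id = c("a", "b", "c"),
                                 uiv = c("T4", "T4", "T2"),
                                 liv = c("L1", "L1", "T12")))
  g <- assign_fusion_groups(fus)
  po <- c(a = 3L, b = 3L, c = 1L)
  ep <- c(a = 1L, b = 1L, c = 2L)
  p <- build_paths(po, ep, g)
  # group numbering is anatomical: T2-T12 -> 1, T4-L1 -> 2
  expect_identical(p$path[p$patient_id == "a"], "PO3-EP1-F2")
  expect_identical(p$path[p$patient_id == "a"], p$path[p$patient_id == "b"])
  expect_identical(p$path[p$patient_id == "c"], "PO1-EP2-F1")

  # permutation of patient order never changes any path
  g2 <- assign_fusion_groups(fus[c(3, 1, 2), ])
  p2 <- build_paths(po, ep, g2)
  expect_identical(p2$path[match(p$patient_id, p2$patient_id)], p$path)

  expect_error(build_paths(po[-1], ep, g), "no PO cluster label for patient 'a'")
  expect_error(build_paths(po, ep[-2], g), "no EP cluster label for patient 'b'")
})

test_that("fusion groups with the same modal outcome merge within a stratum", {
  # one (PO, EP) stratum, three fusion groups: groups 1 and 2 share modal
  # outcome 1, group 3 is modally 2
  fus <- read_fusions(data.frame(
    patient_id = sprintf("p%02d", 1:9),
    uiv = rep(c("T2", "T3", "T4"), each = 3),
    liv = rep("T12", 9)))
  g <- assign_fusion_groups(fus)
  po <- setNames(rep(1L, 9), fus$patient_id)
  ep <- setNames(rep(1L, 9), fus$patient_id)
  y2 <- setNames(c(1L, 1L, 2L, 1L, 1L, 1L, 2L, 2L, 1L), fus$patient_id)
  p <- build_paths(po, ep, g)
  m <- merge_equivalent_fusion_groups(p, y2)
  expect_identical(unique(m$path[m$fusion_group %in% c(1, 2)]), "PO1-EP1-F1,2")
  expect_identical(unique(m$path[m$fusion_group == 3]), "PO1-EP1-F3")
  # merging preserves the total patient count
  expect_identical(nrow(m), nrow(p))
  tab <- path_outcome_table(m, y2)
  expect_identical(sum(tab), 9L)
  expect_identical(unname(tab["PO1-EP1-F1,2", ]), c(5L, 1L))

  # different modal outcomes stay unmerged
  y2b <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L), fus$patient_id)
  mb <- merge_equivalent_fusion_groups(p, y2b)
  expect_identical(sort(unique(mb$path)),
                   c("PO1-EP1-F1", "PO1-EP1-F2", "PO1-EP1-F3"))
})
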