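test_that("class_rule_config enforces a disjoint hydrophobic set", {
  cfg <- class_rule_config()
  expect_false(any(c("S", "T", "D", "E") %in% cfg$phi))
  expect_error(class_rule_config(phi = c("A", "S")), "S/T/D/E")
  expect_error(class_rule_config(phi = character(0)), "non-empty")
})

test_that("truncate_peptide keeps the C-terminal residues", {
  expect_equal(truncate_peptide("AAKETWLVTSDV"), "KETWLVTSDV")
  expect_equal(truncate_peptide("ETWLVTSV"), "ETWLVTSV")  # shorter kept
  expect_equal(truncate_peptide("AAAAB", class_rule_config(truncation_length = 2)),
               "AB")
  expect_error(truncate_peptide(""), "empty")
})

test_that("peptide_class follows the C-terminal motif rules", {
  expect_equal(as.character(peptide_class("KETWLVETSV")), "I")   # T at -2
  expect_equal(as.character(peptide_class("GGYKV")), "II")       # Y at -2
  expect_equal(as.character(peptide_class("QQEDV")), "III")      # D at -2
  expect_equal(as.character(peptide_class("AATKG")), "unclassified")
  expect_error(peptide_class("AV"), "length")
})

test_that("peptide_class ignores residues before position -2", {
  withr::with_seed(5, {
    for (i in 1:25) {
      tail3 <- c(sample(c("S", "T"), 1), sample(AA20, 1), "V")
      a <- paste(c(sample(AA20, 7, TRUE), tail3), collapse = "")
      b <- paste(c(sample(AA20, 7, TRUE), tail3), collapse = "")
      expect_equal(peptide_class(a), peptide_class(b))
    }
  })
})

test_that("the three class rules are mutually exclusive under any valid phi", {
  cfg <- class_rule_config()
  # position -2 determines the branch; phi excludes S/T/D/E by invariant
  pm2_sets <- list(I = c("S", "T"), II = cfg$phi, III = c("D", "E"))
  for (cls in names(pm2_sets)) {
    for (r in pm2_sets[[cls]]) {
      got <- as.character(peptide_class(paste0("AAA", r, "KV"), cfg))
      expect_equal(got, cls)
    }
  }
})

test_that("assign_domain_classes applies the promiscuity rule", {
  peptides <- tibble::tibble(
    id = c("pI1", "pI2", "pII", "pIII"),
    seq = c("AAAAAAATKV", "AAAAAAASGV", "AAAAAAAYKV", "AAAAAAAEKV")
  )
  mk <- function(pairs, labels) tibble::tibble(
    pdz_id = vapply(pairs, `[[`, "", 1),
    peptide_id = vapply(pairs, `[[`, "", 2),
    label = factor(labels, levels = c("binding", "non-binding"))
  )
  # binds two class-I peptides -> I
  one <- assign_domain_classes(
    mk(list(c("d", "pI1"), c("d", "pI2")), c("binding", "binding")),
    peptides)
  expect_equal(as.character(one$class), "I")
  # binds class I and class II -> I-II
  both <- assign_domain_classes(
    mk(list(c("d", "pI1"), c("d", "pII")), c("binding", "binding")),
    peptides)
  expect_equal(as.character(both$class), "I-II")
  # only class III / non-binding evidence -> unassigned
  un <- assign_domain_classes(
    mk(list(c("d", "pIII"), c("d", "pI1")), c("binding", "non-binding")),
    peptides)
  expect_equal(as.character(un$class), "unassigned")
})

test_that("adding a class-II binder to a class-I domain yields I-II, never II", {
  peptides <- tibble::tibble(
    id = c("pI", "pII"), seq = c("AAAAAAATKV", "AAAAAAAYKV"))
  base <- tibble::tibble(
    pdz_id = "d", peptide_id = "pI",
    label = factor("binding", levels = c("binding", "non-binding")))
  grown <- dplyr::bind_rows(base, tibble::tibble(
    pdz_id = "d", peptide_id = "pII",
    label = factor("binding", levels = c("binding", "non-binding"))))
  expect_equal(as.character(assign_domain_classes(base, peptides)$class), "I")
  expect_equal(as.character(assign_domain_classes(grown, peptides)$class),
               "I-II")
})

test_that("interaction datasets have the documented dimensions", {
  inter <- tibble::tibble(
    pdz_id = c("d1", "d2"), peptide_id = c("p1", "p2"),
    label = factor(c("binding", "non-binding"),
                   levels = c("binding", "non-binding")))
  tri <- build_interaction_dataset(inter, toy_domains(), toy_peptides(), n = 3)
  expect_equal(sum(grepl("^(pdz|pep)_tg_", names(tri))), 686)
  bi <- build_interaction_dataset(inter, toy_domains(), toy_peptides(), n = 2)
  expect_equal(sum(grepl("^(pdz|pep)_bg_", names(bi))), 98)
  # each block sums to 1 independently -> rows total 2
  blocks <- as.matrix(tri[grepl("^pdz_tg_", names(tri))])
  expect_equal(unname(rowSums(blocks)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(rowSums(as.matrix(tri[grepl("_tg_", names(tri))]))),
               c(2, 2), tolerance = 1e-9)
  bad <- dplyr::mutate(inter, peptide_id = c("p1", "missing_pep"))
  expect_error(build_interaction_dataset(bad, toy_domains(), toy_peptides()),
               "missing_pep")
})

test_that("class datasets are domain-only with 343 or 49 features", {
  rec <- tibble::tibble(pdz_id = c("d1", "d2"), class = c("I", "I-II"))
  tri <- build_class_dataset(rec, toy_domains(), n = 3)
  expect_equal(sum(grepl("^pdz_tg_", names(tri))), 343)
  expect_false(any(grepl("^pep_", names(tri))))
  bi <- build_class_dataset(rec, toy_domains(), n = 2)
  expect_equal(sum(grepl("^pdz_bg_", names(bi))), 49)
  expect_error(build_class_dataset(
    tibble::tibble(pdz_id = "d1", class = "IV"), toy_domains()),
    "unknown class")
})
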