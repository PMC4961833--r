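test_that("tokenization rotates at the first comma and case-folds", {
  expect_identical(tokenize_disease_name("Diabetes, Type 2"),
                   c("type", "2", "diabetes"))
  expect_identical(tokenize_disease_name("Leukemia"), "leukemia")
  expect_identical(tokenize_disease_name("Testicular Neoplasms"),
                   c("testicular", "neoplasms"))
  # later commas are plain separators; punctuation is stripped
  expect_identical(tokenize_disease_name("Anemia, Sickle-Cell, Severe"),
                   c("sickle", "cell", "severe", "anemia"))
  expect_error(tokenize_disease_name("   "), "non-blank")
})

test_that("initial values halve back-to-front, first duplicating second,
           and sum to 1", {
  expect_equal(assign_initial_values(c("type", "2", "diabetes", "mellitus")),
               c(0.125, 0.125, 0.25, 0.5))
  expect_equal(assign_initial_values("leukemia"), 1)
  expect_equal(assign_initial_values(c("type", "2", "diabetes")),
               c(0.25, 0.25, 0.5))
  expect_equal(assign_initial_values(c("a", "b")), c(0.5, 0.5))
  for (k in 1:8) {
    iv <- assign_initial_values(letters[seq_len(k)])
    expect_equal(sum(iv), 1)
    expect_true(all(diff(iv) >= 0)) # non-increasing toward the front
  }
})

test_that("disease-name similarity reproduces the worked pairs and its
           invariants", {
  expect_equal(disease_similarity("Diabetes, Type 2",
                                  "Type 2 Diabetes Mellitus"), 0.5)
  expect_equal(disease_similarity("Testicular Neoplasms",
                                  "Testicular Disease"), 0.25)
  expect_equal(disease_similarity("Leukemia", "Leukemia"), 1)
  expect_equal(disease_similarity("Leukemia", "Arthritis"), 0)
  # symmetry + range over random word pairs
  set.seed(11)
  words <- c("renal", "cell", "acute", "chronic", "anemia", "disease",
             "type", "2", "syndrome")
  for (i in 1:30) {
    a <- paste(sample(words, sample(1:4, 1)), collapse = " ")
    b <- paste(sample(words, sample(1:4, 1)), collapse = " ")
    s <- disease_similarity(a, b)
    expect_equal(s, disease_similarity(b, a))
    expect_true(s >= 0 && s <= 1)
    if (setequal(tokenize_disease_name(a), tokenize_disease_name(b))) {
      expect_equal(s, 1)
    }
  }
})

test_that("the cascade assigns the four tiers and unmapped as expected", {
  onto <- toy_ontology()
  th <- toy_thesauri()
  m <- map_disease("Leukemia", onto, th)
  expect_identical(m$tier, "direct")
  expect_equal(m$score, 1)
  expect_identical(m$matched_terms$term_id, "DOID:1")

  m <- map_disease("Diabetes, Type 2", onto, th)
  expect_identical(m$tier, "half_ambiguous")
  expect_equal(m$score, 0.5)
  expect_identical(m$matched_terms$term_id, "DOID:2")

  m <- map_disease("Sleep Disorders", onto, th)
  expect_identical(m$tier, "xref")
  expect_equal(m$score, 1)
  expect_identical(m$matched_terms$term_id, "DOID:3")

  m <- map_disease("Testicular Neoplasms", onto, th, ambiguous_floor = 0.2)
  expect_identical(m$tier, "ambiguous")
  expect_equal(m$score, 0.25)
  expect_identical(m$matched_terms$term_id, "DOID:4")

  m <- map_disease("bqz77 assay", onto, th)
  expect_identical(m$tier, "unmapped")
  expect_equal(m$score, 0)
  expect_equal(nrow(m$matched_terms), 0L)

  # direct matches also fire on synonyms
  onto2 <- mk_ontology(mk_term("DOID:9", "Hepatic Cancer",
                               synonyms = "Liver Cancer"))
  expect_identical(map_disease("liver cancer", onto2)$tier, "direct")
})

test_that("adding ontology terms never demotes a name to a lower tier", {
  tiers <- c(unmapped = 0, ambiguous = 1, half_ambiguous = 2, xref = 2,
             direct = 3)
  onto <- toy_ontology()
  th <- toy_thesauri()
  extra <- mk_term("DOID:99", "Neoplasms Panel")
  for (nm in c("Leukemia", "Diabetes, Type 2", "Sleep Disorders",
               "Testicular Neoplasms", "bqz77 assay")) {
    before <- map_disease(nm, onto, th)
    after <- map_disease(nm, c_onto(onto, extra), th)
    expect_gte(tiers[[after$tier]], tiers[[before$tier]])
  }
})

test_that("ambiguous tier equals the exhaustive argmax oracle", {
  set.seed(23)
  words <- c("renal", "cell", "acute", "chronic", "anemia", "disease",
             "carcinoma", "type", "syndrome", "deficiency", "virus",
             "bone", "skin", "blood", "lung")
  for (rep in 1:20) {
    n_terms <- sample(5:50, 1)
    onto <- do.call(mk_ontology, lapply(seq_len(n_terms), function(i) {
      mk_term(sprintf("DOID:%03d", i),
              paste(sample(words, sample(1:3, 1)), collapse = " "))
    }))
    # ids must be unique names; names may repeat across terms
    query <- paste(sample(words, sample(1:3, 1)), collapse = " ")
    got <- map_disease(query, onto, ambiguous_floor = 1e-6,
                       tier_order = "ambiguous")
    q <- token_list(query)
    scores <- vapply(onto, function(t) {
      tt <- tokenize_disease_name(t$name)
      if (!any(q$tokens %in% tt)) return(NA_real_)
      disease_similarity(q, t$name)
    }, numeric(1))
    if (all(is.na(scores)) || max(scores, na.rm = TRUE) < 1e-6) {
      expect_identical(got$tier, "unmapped")
    } else {
      best <- max(scores, na.rm = TRUE)
      expect_equal(got$score, best)
      expect_setequal(got$matched_terms$term_id,
                      names(onto)[!is.na(scores) & scores == best])
    }
  }
})

test_that("mapping reports round-trip the tier table and unmapped chart", {
  onto <- toy_ontology()
  maps <- map_diseases(c("Leukemia", "Testicular Neoplasms", "bqz77 assay"),
                       onto, toy_thesauri())
  f <- tempfile(fileext = ".tsv")
  u <- tempfile(fileext = ".txt")
  write_mapping_report(maps, f, u)
  rep <- utils::read.delim(f, colClasses = "character")
  expect_setequal(rep$tier, c("direct", "ambiguous", "unmapped"))
  expect_identical(readLines(u), "bqz77 assay")
})
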