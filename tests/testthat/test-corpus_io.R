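test_that("inversion is a fixed involution over the 12 fine types", {
  for (r in fine_relation_types()) {
    expect_equal(invert_relation(invert_relation(r)), r)
  }
  expect_equal(invert_relation("Overlap_After"), "Before_Overlap")
  expect_equal(invert_relation("Before_Overlap"), "Overlap_After")
  expect_equal(invert_relation("Simultaneous"), "Simultaneous")
  expect_equal(invert_relation("Begins"), "Begun_By")
  expect_equal(invert_relation("Ends"), "Ended_By")
  expect_equal(invert_relation("During"), "During_Inv")
  expect_error(invert_relation("BEFORE3"), "taxonomy")
  expect_error(invert_relation("NO_RELATION"), "taxonomy")
})

test_that("the 12-to-3 mapping is total and inverts the four reversed types", {
  link <- function(r) data.frame(from = "e1", to = "e2", relation = r,
                                 stringsAsFactors = FALSE)
  # the merge groups
  for (r in c("Overlap", "Simultaneous", "During")) {
    out <- map_12_to_3(link(r))
    expect_equal(out$relation, "OVERLAP3")
  }
  for (r in c("Before", "Before_Overlap", "Ended_By")) {
    expect_equal(map_12_to_3(link(r))$relation, "BEFORE3")
  }
  for (r in c("After", "Begun_By")) {
    expect_equal(map_12_to_3(link(r))$relation, "AFTER3")
  }
  # an Ends instance is first replaced by the reversed Ended_By instance
  out <- map_12_to_3(link("Ends"))
  expect_equal(out$from, "e2")
  expect_equal(out$to, "e1")
  expect_equal(out$relation, "BEFORE3")
  # endpoints unchanged for the non-inverted group
  out <- map_12_to_3(link("Simultaneous"))
  expect_equal(c(out$from, out$to), c("e1", "e2"))
  # totality: image is exactly the three broad types
  img <- vapply(fine_relation_types(),
                function(r) map_12_to_3(link(r))$relation, "")
  expect_setequal(unique(img), broad_relation_types())
})

test_that("mapping a pair and its inverted reading agree", {
  for (r in fine_relation_types()) {
    a <- map_12_to_3(data.frame(from = "x", to = "y", relation = r,
                                stringsAsFactors = FALSE))
    b <- map_12_to_3(data.frame(from = "y", to = "x",
                                relation = invert_relation(r),
                                stringsAsFactors = FALSE))
    # same ordered broad assertion, possibly read in opposite directions
    same_dir <- identical(c(a$from, a$to, a$relation),
                          c(b$from, b$to, b$relation))
    inv3 <- c(BEFORE3 = "AFTER3", AFTER3 = "BEFORE3", OVERLAP3 = "OVERLAP3")
    opp_dir <- identical(c(a$from, a$to, unname(inv3[a$relation])),
                         c(b$to, b$from, b$relation))
    expect_true(same_dir || opp_dir, label = paste("agree for", r))
  }
})

test_that("an annotated document parses with verified spans and links", {
  text <- "He was ready for discharge home on postoperative day 3."
  xml <- paste0(
    '<ClinicalNarrativeTemporalAnnotation id="ex1"><TEXT>', text,
    '</TEXT><TAGS>',
    '<EVENT id="E0" start="17" end="26" text="discharge" type="OCCURRENCE"',
    ' polarity="POS" modality="FACTUAL"/>',
    '<TIMEX3 id="T0" start="35" end="54" text="postoperative day 3"',
    ' type="DATE" val="POSTOP-DAY-3" mod="NA"/>',
    '<TLINK id="L0" fromID="E0" toID="T0" type="SIMULTANEOUS"/>',
    '</TAGS></ClinicalNarrativeTemporalAnnotation>')
  f <- tempfile(fileext = ".xml")
  writeLines(xml, f)
  doc <- parse_i2b2_xml(f)
  expect_equal(nrow(doc$events), 1L)
  expect_equal(nrow(doc$times), 1L)
  expect_equal(nrow(doc$tlinks), 1L)
  expect_equal(doc$tlinks$relation, "Simultaneous")
  expect_equal(doc$events$text, "discharge")
  expect_equal(doc$times$text, "postoperative day 3")
})

test_that("parse errors are informative", {
  f <- tempfile(fileext = ".xml")
  writeLines("<a><b></a>", f)
  expect_error(parse_i2b2_xml(f), "parse error")
  # span/text mismatch
  xml <- paste0('<R id="x"><TEXT>abcdef</TEXT><TAGS>',
                '<EVENT id="E0" start="0" end="3" text="zzz" type="TEST"',
                ' polarity="POS" modality="FACTUAL"/></TAGS></R>')
  writeLines(xml, f)
  expect_error(parse_i2b2_xml(f), "E0")
  # unknown relation string
  xml <- paste0('<R id="x"><TEXT>abcdef</TEXT><TAGS>',
                '<EVENT id="E0" start="0" end="3" text="abc" type="TEST"',
                ' polarity="POS" modality="FACTUAL"/>',
                '<EVENT id="E1" start="3" end="6" text="def" type="TEST"',
                ' polarity="POS" modality="FACTUAL"/>',
                '<TLINK id="L0" fromID="E0" toID="E1" type="WIBBLE"/>',
                '</TAGS></R>')
  writeLines(xml, f)
  expect_error(parse_i2b2_xml(f), "taxonomy")
})

test_that("documents round-trip through XML structurally unchanged", {
  co <- generate_corpus(3, 2, sentences_per_doc = 4)
  for (d in names(co$docs)) {
    f <- tempfile(fileext = ".xml")
    write_i2b2_xml(co$docs[[d]], f)
    back <- parse_i2b2_xml(f)
    expect_identical(back$text, co$docs[[d]]$text)
    expect_identical(back$events, co$docs[[d]]$events)
    expect_identical(back$times, co$docs[[d]]$times)
    expect_identical(back$tlinks[, c("from", "to", "relation")],
                     co$docs[[d]]$tlinks[, c("from", "to", "relation")])
    expect_identical(back$sectimes, co$docs[[d]]$sectimes)
    # second round trip is the identity
    f2 <- tempfile(fileext = ".xml")
    write_i2b2_xml(back, f2)
    expect_identical(parse_i2b2_xml(f2)$events, back$events)
  }
})

test_that("zero-TLINK documents and sentinel links are handled", {
  doc <- clinical_document(
    "empty", "some text here",
    events = data.frame(id = "E0", start = 0L, end = 4L, text = "some",
                        type = "TEST", polarity = "POS",
                        modality = "FACTUAL", stringsAsFactors = FALSE))
  f <- tempfile(fileext = ".xml")
  write_i2b2_xml(doc, f)
  back <- parse_i2b2_xml(f)
  expect_equal(nrow(back$tlinks), 0L)
  # NO_RELATION is never serialized
  doc$events <- rbind(doc$events, data.frame(
    id = "E1", start = 5L, end = 9L, text = "text", type = "TEST",
    polarity = "POS", modality = "FACTUAL", stringsAsFactors = FALSE))
  doc$tlinks <- data.frame(id = "L0", from = "E0", to = "E1",
                           relation = "NO_RELATION", origin = "RULE",
                           stringsAsFactors = FALSE)
  expect_error(write_i2b2_xml(doc, f), "taxonomy")
})

test_that("document invariants are enforced", {
  expect_error(clinical_document(
    "bad", "abc",
    events = data.frame(id = "E0", start = 0L, end = 9L, text = "abc",
                        type = "TEST", polarity = "P", modality = "F",
                        stringsAsFactors = FALSE)),
    "integrity")
  expect_error(clinical_document(
    "bad", "abcdef",
    events = data.frame(id = c("E0", "E0"), start = c(0L, 3L),
                        end = c(3L, 6L), text = c("abc", "def"),
                        type = "TEST", polarity = "P", modality = "F",
                        stringsAsFactors = FALSE)),
    "duplicate")
})
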