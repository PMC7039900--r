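# toy_model() exon layout: 1001-1080 (80 nt), 2001-2200 (200 nt),
# 3001-3120 (120 nt); introns 1081-2000 and 2201-3000

test_that("canonical junction sets have n-1 junctions", {
  expect_equal(nrow(canonical_junctions(toy_model())), 2L)
  m2 <- gene_model("G", "chr1", "+", c(1, 200), c(100, 300), "T")
  expect_equal(nrow(canonical_junctions(m2)), 1L)
  m1 <- gene_model("G", "chr1", "+", 1, 100, "T")
  expect_equal(nrow(canonical_junctions(m1)), 0L)
  # minus-strand intron 1 sits between transcript exons 1 and 2
  cjm <- canonical_junctions(toy_model("-"))
  expect_equal(cjm$start[1], 2201L)
  expect_equal(cjm$end[1], 3000L)
})

test_that("full exon skips are classified with skipped exons and denominators", {
  m <- toy_model()
  r <- classify_junction(toy_junction(1081, 3000), m)
  expect_equal(r$status, "event")
  ev <- r$event
  expect_equal(ev$type, "ESF")
  expect_equal(ev$skipped_exons, "2")
  expect_equal(ev$deleted_length, 200L)  # length of exon 2
  expect_equal(ev$inserted_length, 0L)
  expect_equal(ev$name, "r.81_280del")
  expect_equal(length(strsplit(ev$denominator, ",")[[1]]), 2L)
  # canonical interpretation wins at exact boundaries
  expect_equal(classify_junction(toy_junction(1081, 2000), m)$status,
               "canonical")
})

test_that("partial exon skips measure the truncated length and frame", {
  m <- toy_model()
  # acceptor shifted 17 nt into exon 2
  r <- classify_junction(toy_junction(1081, 2017), m)
  expect_equal(r$event$type, "ESP")
  expect_equal(r$event$deleted_length, 17L)
  expect_equal(r$event$frame, "frameshift")
  expect_equal(r$event$name, "r.81_97del")
  # donor shifted 21 nt into exon 1 (in-frame)
  r2 <- classify_junction(toy_junction(1060, 2000), m)
  expect_equal(r2$event$type, "ESP")
  expect_equal(r2$event$deleted_length, 21L)
  expect_equal(r2$event$frame, "in-frame")
  expect_equal(r2$event$name, "r.60_80del")
})

test_that("partial intron retention is IP with the retained length", {
  m <- toy_model()
  # acceptor 8 nt into intron 1: retains the last 8 intronic bases
  r <- classify_junction(toy_junction(1081, 1992), m)
  expect_equal(r$event$type, "IP")
  expect_equal(r$event$inserted_length, 8L)
  expect_equal(r$event$frame, "frameshift")
  expect_equal(r$event$name, "r.80_81ins81-8_81-1")
  # donor 9 nt into intron 2: in-frame retention after the exon
  r2 <- classify_junction(toy_junction(2210, 3000), m)
  expect_equal(r2$event$inserted_length, 9L)
  expect_equal(r2$event$frame, "in-frame")
  expect_equal(r2$event$name, "r.280_281ins280+1_280+9")
})

test_that("cryptic exons pair two intron-internal junctions", {
  m <- gene_model("G", "chr1", "+", c(1, 10001), c(1000, 11000), "T")
  # intron 1001-10000; cryptic exon of 63 nt at 4001-4063
  jx <- rbind(toy_junction(1001, 4000), toy_junction(4064, 10000))
  ev <- detect_events(m, jx)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "IC")
  expect_equal(ev$inserted_length, 63L)
  expect_equal(ev$frame, "in-frame")
  expect_equal(ev$name, "r.1000_1001ins1000+3001_1000+3063")
  expect_equal(length(strsplit(ev$supporting, ",")[[1]]), 2L)
  # a lone candidate stays a partial intronic insertion
  ev1 <- detect_events(m, toy_junction(4064, 10000))
  expect_equal(ev1$type, "IP")
  # junctions implying an empty cryptic exon are not paired
  jx0 <- rbind(toy_junction(1001, 4000), toy_junction(4001, 10000))
  expect_false("IC" %in% detect_events(m, jx0)$type)
})

test_that("event names reproduce the r.-style patterns on matched layouts", {
  # exon 2 occupies transcript 5075..5152 (a 78-nt exon)
  m <- gene_model("G", "chr1", "+", c(1, 10001, 20001),
                  c(5074, 10078, 21000), "T")
  ev <- detect_events(m, toy_junction(5075, 20000))
  expect_equal(ev$name, "r.5075_5152del")
  # ESP deleting transcript 11..23 via a novel donor 13 nt into exon 1
  m2 <- gene_model("G", "chr1", "+", c(1, 1001), c(23, 1500), "T")
  ev2 <- detect_events(m2, toy_junction(11, 1000))
  expect_equal(ev2$type, "ESP")
  expect_equal(ev2$name, "r.11_23del")
  # IP retaining the last 4 intronic bases before transcript position 577
  m3 <- gene_model("G", "chr1", "+", c(1, 1001), c(576, 1500), "T")
  ev3 <- detect_events(m3, toy_junction(577, 996))
  expect_equal(ev3$name, "r.576_577ins577-4_577-1")
})

test_that("classification is invariant under strand mirroring", {
  # same exon layout on both strands; junctions are strand-agnostic introns
  cases <- list(c(1081, 3000),   # full skip of exon 2
                c(1081, 2017),   # partial skip
                c(1081, 1992),   # intron retention
                c(2201, 3000))   # canonical (intron 2 on +, intron 1 on -)
  for (co in cases) {
    rp <- classify_junction(toy_junction(co[1], co[2], strand = "*"),
                            toy_model("+"))
    rm_ <- classify_junction(toy_junction(co[1], co[2], strand = "*"),
                             toy_model("-"))
    expect_equal(rp$status, rm_$status)
    if (rp$status == "event") {
      expect_equal(rp$event$type, rm_$event$type)
      expect_equal(rp$event$deleted_length, rm_$event$deleted_length)
      expect_equal(rp$event$inserted_length, rm_$event$inserted_length)
      expect_equal(rp$event$frame, rm_$event$frame)
    }
  }
})

test_that("every canonical junction of random models classifies canonical", {
  for (seed in 1:20) {
    m <- random_model(seed)
    cj <- canonical_junctions(m)
    for (i in seq_len(nrow(cj))) {
      r <- classify_junction(
        toy_junction(cj$start[i], cj$end[i], strand = m$strand,
                     chrom = m$chrom), m)
      expect_equal(r$status, "canonical")
    }
  }
})

test_that("frame status is the net length change mod 3", {
  # long intron and wide exons accommodate retentions/truncations up to 300
  m <- gene_model("G", "chr1", "+", c(1, 2001), c(1000, 3000), "T")
  for (d in c(1:5, 297:300)) {
    ip <- classify_junction(toy_junction(1001, 2000 - d), m)$event
    expect_equal(ip$frame, if (d %% 3 == 0) "in-frame" else "frameshift")
    esp <- classify_junction(toy_junction(1001 - d, 2000), m)$event
    expect_equal(esp$frame, if (d %% 3 == 0) "in-frame" else "frameshift")
  }
})

test_that("junctions with no event interpretation are reported unassigned", {
  m <- toy_model()
  # both ends inside exons (exitron-like)
  ev <- detect_events(m, toy_junction(1030, 2100))
  expect_equal(nrow(ev), 0L)
  expect_equal(attr(ev, "unassigned")$reason, "no canonical anchor")
  # wrong strand of a stranded gene
  ev2 <- detect_events(m, toy_junction(1081, 3000, strand = "-"))
  expect_equal(attr(ev2, "unassigned")$reason, "wrong strand")
})

test_that("events touching excluded exons are dropped from detection", {
  m <- toy_model(excluded = 2)
  ev <- detect_events(m, toy_junction(1081, 3000))  # skips excluded exon 2
  expect_equal(nrow(ev), 0L)
  # naming an event that slipped past the filter is a hard error
  esp <- detect_events(toy_model(), toy_junction(1081, 2017))
  expect_error(name_event(esp, m), "excluded")
  # events elsewhere in the gene are unaffected by the exclusion
  m3 <- gene_model("G", "chr1", "+", c(1, 1001, 2001, 3001),
                   c(500, 1500, 2500, 3500), "T", excluded_exons = 4)
  expect_equal(detect_events(m3, toy_junction(501, 2000))$type, "ESF")
})

test_that("ES aggregates combine full and partial skipping per exon", {
  m <- gene_model("G", "chr1", "+", c(1, 1001, 2001, 3001),
                  c(500, 1500, 2500, 3500), "T")
  jx <- rbind(toy_junction(1501, 3000),  # ESF exon 3
              toy_junction(1501, 2018))  # ESP exon 3
  ev <- detect_events(m, jx)
  agg <- merge_es(ev)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$type, "ES")
  expect_equal(agg$n_components, 2L)
  expect_equal(agg$target_exon, 3L)
  # ESF alone still forms its aggregate; no events -> no rows
  expect_equal(merge_es(ev[ev$type == "ESF", , drop = FALSE])$n_components, 1L)
  expect_equal(nrow(merge_es(ev[0, ])), 0L)
})
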