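test_that("CPM normalisation rescales to a million and guards its units", {
  tr <- coverage_track(list(chrA = c(rep(0, 4), 20, rep(1, 5)),
                            chrB = rep(1999975 / 10, 10)), units = "raw")
  cpm <- cpm_normalize(tr)  # total is 2e6
  expect_equal(cpm$values$chrA[5], 10)
  expect_equal(polkin:::track_total(cpm), 1e6)
  expect_error(cpm_normalize(cpm), "already normalised")

  uni <- cpm_normalize(coverage_track(list(c1 = rep(3, 100)), units = "raw"))
  expect_true(all(uni$values$c1 == 1e6 / 100))
  # scale invariance: depth has no effect on CPM
  uni2 <- cpm_normalize(coverage_track(list(c1 = rep(12, 100)),
                                       units = "raw"))
  expect_equal(uni$values, uni2$values)
})

test_that("background subtraction is elementwise, signed and type-checked", {
  a <- cpm_normalize(coverage_track(list(c1 = c(5, 5, 10)), units = "raw"))
  b <- cpm_normalize(coverage_track(list(c1 = c(2, 5, 13)), units = "raw"))
  d <- background_subtract(a, b)
  expect_equal(d$units, "delta")
  expect_equal(d$values$c1, a$values$c1 - b$values$c1)
  expect_true(any(d$values$c1 < 0))
  expect_true(all(background_subtract(a, a)$values$c1 == 0))
  expect_error(background_subtract(a, coverage_track(list(c1 = 1:3))),
               "CPM")
  cc <- cpm_normalize(coverage_track(list(c2 = c(1, 2, 3)), units = "raw"))
  expect_error(background_subtract(a, cc), "different references")
})

test_that("gene regions reproduce the worked offsets with constant widths", {
  g <- list(seqname = "chr1", strand = "+", tss = 1000, tes = 3000)
  reg <- gene_regions(g)
  expect_equal(reg$start[reg$region == "uas"], 500)
  expect_equal(reg$end[reg$region == "uas"], 850)
  expect_equal(reg$start[reg$region == "promoter"], 850)
  expect_equal(reg$end[reg$region == "promoter"], 1026)
  expect_equal(reg$start[reg$region == "transcript"], 1026)
  expect_equal(reg$end[reg$region == "transcript"], 2925)
  expect_equal(reg$start[reg$region == "terminator"], 2925)
  expect_equal(reg$end[reg$region == "terminator"], 3151)

  widths <- function(r) stats::setNames(r$end - r$start, r$region)
  for (tss in c(2000, 5000)) for (len in c(500, 2000)) {
    w <- widths(gene_regions(list(seqname = "c", strand = "+",
                                  tss = tss, tes = tss + len)))
    expect_equal(unname(w[c("uas", "promoter", "terminator")]),
                 c(350, 176, 226))
  }
  expect_error(gene_regions(list(seqname = "c", strand = "+",
                                 tss = 1000, tes = 1100)), "too short")
})

test_that("minus-strand regions are the mirror image about the gene axis", {
  plus <- gene_regions(list(seqname = "c", strand = "+",
                            tss = 5000, tes = 7000))
  minus <- gene_regions(list(seqname = "c", strand = "-",
                             tss = 7000, tes = 5000))
  # reflect half-open [s, e) about the axis: c -> tss + tes - c
  T <- 5000 + 7000
  for (rg in plus$region) {
    p <- plus[plus$region == rg, ]
    m <- minus[minus$region == rg, ]
    expect_equal(m$start, T - p$end + 1)
    expect_equal(m$end, T - p$start + 1)
  }
  # UAS of a minus-strand gene lies at larger coordinates than its promoter
  expect_gt(minus$start[minus$region == "uas"],
            minus$end[minus$region == "promoter"] - 1)
  # involution: mirroring the mirrored gene restores the original intervals
  again <- gene_regions(list(seqname = "c", strand = "+",
                             tss = 5000, tes = 7000))
  expect_identical(plus, again)
})

test_that("region means are per-bp and feed the fit-ready vector", {
  g <- list(seqname = "c", strand = "+", tss = 1000, tes = 3000)
  reg <- gene_regions(g)
  v <- rep(2.5, 4000)
  tr <- coverage_track(list(c = v), units = "raw")
  rm1 <- region_means(tr, reg)
  expect_true(all(rm1$mean == 2.5))

  v2 <- numeric(4000); v2[851:1026] <- 4  # promoter only
  rm2 <- region_means(coverage_track(list(c = v2), units = "raw"), reg)
  expect_equal(rm2$mean[rm2$region == "promoter"], 4)
  expect_true(all(rm2$mean[rm2$region != "promoter"] == 0))

  genes <- data.frame(seqname = "c", strand = "+", tss = 1000, tes = 3000)
  emp <- track_region_occupancy(coverage_track(list(c = v2), units = "raw"),
                                genes, gene_class = "STM")
  expect_s3_class(emp, "region_occupancy")
  expect_length(emp, 4)
  expect_equal(unname(emp["promoter"]), 4)
  expect_warning(
    region_means(tr, data.frame(region = "x", seqname = "c",
                                start = 3900, end = 4200)), "clipped")
})

test_that("metagene profiles are replicate-linear and length-invariant", {
  flank <- 100; nbins <- 50
  mk_gene <- function(tss, len)
    data.frame(seqname = "c", strand = "+", tss = tss, tes = tss + len - 1)
  # shape: flank constant 1, first half of body 0, second half 2
  body_vals <- function(len) c(rep(0, len / 2), rep(2, len / 2))
  v <- rep(1, 3000)
  v[(501):(500 + 200)] <- body_vals(200)
  v[(1501):(1500 + 400)] <- body_vals(400)
  genes <- rbind(mk_gene(500, 200), mk_gene(1500, 400))
  tr <- coverage_track(list(c = v), units = "raw")
  prof <- metagene_profile(tr, genes, flank = flank, nbins = nbins)
  expect_equal(nrow(prof), 3 * nbins)
  expect_equal(attr(prof, "n_genes"), 2)
  body <- prof$signal[prof$segment == "body"]
  # identical per-segment shape at different lengths: exact step profile
  expect_true(all(body[1:(nbins / 2)] == 0))
  expect_true(all(body[(nbins / 2 + 1):nbins] == 2))

  # replicate averaging comes first and is linear
  tr2 <- coverage_track(list(c = 3 * v), units = "raw")
  prof2 <- metagene_profile(list(tr, tr2), genes, flank = flank,
                            nbins = nbins)
  expect_equal(prof2$signal, 2 * prof$signal)

  # uniform signal: flat profile
  flat <- metagene_profile(coverage_track(list(c = rep(7, 3000))),
                           mk_gene(500, 200), flank = flank, nbins = nbins)
  expect_true(all(flat$signal == 7))

  expect_error(suppressMessages(
    metagene_profile(tr, mk_gene(500, 20), flank = flank, nbins = nbins)),
    "no usable genes")
})

test_that("metasite profiles orient, align and smooth as specified", {
  n <- 2001
  v <- numeric(n); v[1001] <- 100  # impulse at 0-based position 1000
  tr <- coverage_track(list(c = v), units = "raw")
  sites <- data.frame(seqname = "c", pos = 1000, strand = "+")
  prof <- metasite_profile(tr, sites, flank = 250, window = 10, step = 5)
  expect_equal(nrow(prof), 99)  # windows fully inside, starts every 5 bp
  # impulse response: nonzero exactly where the window covers the site
  hit <- prof$signal > 0
  expect_equal(sum(hit), 2)     # window 10, step 5: two windows see it
  expect_equal(max(abs(prof$offset[hit])), 4.5)

  # orientation contract: minus-strand sites with mirrored signal match
  v2 <- numeric(n); v2[1001 - 30] <- 100
  v3 <- numeric(n); v3[1001 + 30] <- 100
  p_plus <- metasite_profile(coverage_track(list(c = v2)),
                             data.frame(seqname = "c", pos = 1000,
                                        strand = "+"), flank = 250)
  p_minus <- metasite_profile(coverage_track(list(c = v3)),
                              data.frame(seqname = "c", pos = 1000,
                                         strand = "-"), flank = 250)
  expect_equal(p_plus$signal, p_minus$signal)
  expect_error(suppressMessages(
    metasite_profile(tr, data.frame(seqname = "c", pos = 10,
                                    strand = "+"))),
    "no usable sites")
})

test_that("bedGraph and BED round trips are lossless", {
  v <- numeric(500); v[101:150] <- 3; v[301] <- 7.5
  tr <- coverage_track(list(synthI = v), units = "raw")
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, seqlengths = c(synthI = 500))
  expect_equal(back$values$synthI, v)

  genes <- data.frame(id = c("g1", "g2"), seqname = "synthI",
                      strand = c("+", "-"), tss = c(100, 450),
                      tes = c(220, 300), stringsAsFactors = FALSE)
  fb <- withr::local_tempfile(fileext = ".bed")
  write_genes_bed(genes, fb)
  back2 <- read_genes_bed(fb)
  expect_equal(back2[, c("id", "seqname", "strand", "tss", "tes")],
               genes[, c("id", "seqname", "strand", "tss", "tes")])
})
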