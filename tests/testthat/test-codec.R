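# Wire formats, transport simulation and FIFO alignment.

test_that("SPR sample coding round-trips exhaustively for both boxes", {
  for (box in c("A", "B")) {
    m <- encode_spr_sample(0:4095, box)
    # flag bits: bit7 distinguishes H from L, bit6 carries the box
    expect_true(all(bitwAnd(m[, "high"], 0x80L) == 0x80L))
    expect_true(all(bitwAnd(m[, "low"], 0x80L) == 0L))
    ab <- if (box == "A") 0L else 0x40L
    expect_true(all(bitwAnd(m[, "high"], 0x40L) == ab))
    expect_true(all(bitwAnd(m[, "low"], 0x40L) == ab))
    dec <- decode_spr_stream(as.integer(t(m)))
    expect_identical(dec[[box]], 0:4095)
    expect_identical(dec$diagnostics$orphans, 0L)
    expect_length(dec[[setdiff(c("A", "B"), box)]], 0)
  }
  expect_error(encode_spr_sample(4096, "A"), "range")
  expect_error(encode_spr_sample(-1, "A"), "range")
})

test_that("stream decoder resynchronizes around a missing octet", {
  codes <- c(100L, 2000L, 3000L, 4095L, 0L, 17L, 512L, 1023L)
  m <- encode_spr_sample(codes, "A")
  octets <- as.integer(t(m))
  octets <- octets[-4L]                      # drop the low byte of sample 2
  dec <- decode_spr_stream(octets)
  expect_identical(dec$A, codes[-2L])
  expect_identical(dec$diagnostics$orphans, 1L)
})

test_that("interleaved A and B streams separate losslessly by the AB bit", {
  ca <- c(1L, 2L, 3L, 4L)
  cb <- c(4000L, 4001L, 4002L, 4003L)
  ma <- encode_spr_sample(ca, "A")
  mb <- encode_spr_sample(cb, "B")
  # interleave at octet level: Ah, Bh, Al, Bl, ...
  octets <- as.vector(rbind(ma[, "high"], mb[, "high"], ma[, "low"], mb[, "low"]))
  dec <- decode_spr_stream(octets)
  expect_identical(dec$A, ca)
  expect_identical(dec$B, cb)
  expect_identical(dec$diagnostics$orphans, 0L)
})

test_that("packetizer emits 8-sample packets with 16 wire octets", {
  pkts <- spr_packetize(0:99, "A")
  expect_length(pkts, 12)                    # 96 samples packetized, 4 dropped
  expect_true(all(vapply(pkts, function(p) length(p$samples), integer(1)) == 8))
  expect_length(spr_packet_octets(pkts[[1]]), 16)
  # send times at one packet period cadence
  expect_equal(vapply(pkts, `[[`, numeric(1), "send_time_s"),
               seq(0.04, by = 0.04, length.out = 12))
})

test_that("transport is deterministic, order-preserving and lossy as asked", {
  pkts <- spr_packetize(rep(0:7, 50), "A")
  # lossless zero-jitter: fixed offset
  del <- simulate_transport(pkts, transport_spec(latency_s = 0.003))
  expect_length(del, length(pkts))
  expect_equal(vapply(del, `[[`, numeric(1), "delivery_time_s") -
                 vapply(pkts, `[[`, numeric(1), "send_time_s"),
               rep(0.003, length(pkts)))
  # seeded: bit-reproducible; jitter bounded so order preserved
  spec <- transport_spec(latency_s = 0.005, latency_jitter_s = 0.01,
                         loss_prob = 0.1, seed = 11)
  d1 <- simulate_transport(pkts, spec)
  d2 <- simulate_transport(pkts, spec)
  expect_identical(d1, d2)
  expect_true(!is.unsorted(vapply(d1, `[[`, numeric(1), "delivery_time_s")))
  expect_gt(attr(d1, "n_lost"), 0)
  expect_error(transport_spec(loss_prob = 0.1), "seed")
})

test_that("FIFO aligner delays SPR by one packet period and flags cold start", {
  n <- 400L
  codes <- as.integer(round(2048 + 1000 * sin(2 * pi * (0:(n - 1)) / 64)))
  pk <- spr_packetize(codes, "A")
  del <- simulate_transport(pk, transport_spec())
  fr <- align_frames(rep(2048L, n), rep(2048L, n), del, list())
  # cold start: exactly 8 stale frames at the idle code before delivery
  expect_identical(which(fr$stale_a), 1:8)
  expect_true(all(fr$spra[1:8] == 2048L))
  # afterwards each frame carries the sample acquired 8 frames earlier
  expect_identical(fr$spra[9:n], codes[1:(n - 8)])
  # box B got nothing: all stale
  expect_true(all(fr$stale_b))
})

test_that("one dropped packet yields 8 stale frames then exact realignment", {
  n <- 480L
  codes <- seq_len(n) %% 4096L
  pk <- spr_packetize(codes, "A")
  drop_idx <- 20L
  del <- simulate_transport(pk[-drop_idx], transport_spec())
  fr <- align_frames(rep(0L, n), rep(0L, n), del, list())
  stale <- which(fr$stale_a)
  expect_identical(stale[-(1:8)], (8L * drop_idx + 1L):(8L * drop_idx + 8L))
  # stale frames repeat the last good sample
  expect_true(all(fr$spra[(8L * drop_idx + 1L):(8L * drop_idx + 8L)] ==
                    codes[8L * (drop_idx - 1L)]))
  # no permanent offset: later frames realign to the 8-frame delay
  later <- (8L * drop_idx + 17L):n
  expect_identical(fr$spra[later], codes[later - 8L])
})

test_that("conservation: frames == ECG samples; SPR pops + stales == frames", {
  n <- 400L
  codes <- as.integer((seq_len(n) * 7L) %% 4096L)
  pk <- spr_packetize(codes, "A")
  spec <- transport_spec(loss_prob = 0.2, seed = 3)
  del <- simulate_transport(pk, spec)
  fr <- align_frames(rep(1L, n), rep(2L, n), del, list())
  expect_length(fr$ecg1, n)
  delivered <- sum(vapply(del, function(p) length(p$samples), integer(1)))
  consumed <- n - sum(fr$stale_a)
  expect_lte(consumed, delivered)
  expect_identical(consumed + sum(fr$stale_a), n)
})

test_that("frame wire format round-trips and carries 2000 octets per second", {
  n <- 600L
  set.seed(5)
  fr <- align_frames(sample(0:4095, n, TRUE), sample(0:4095, n, TRUE),
                     simulate_transport(spr_packetize(sample(0:4095, n, TRUE), "A"),
                                        transport_spec()),
                     simulate_transport(spr_packetize(sample(0:4095, n, TRUE), "B"),
                                        transport_spec()))
  octets <- encode_frames(fr)
  expect_length(octets, 10L * n)             # 10 octets / 5 ms = 2000 B/s
  dec <- decode_frames(octets)
  expect_identical(dec$ecg1, fr$ecg1)
  expect_identical(dec$ecg2, fr$ecg2)
  expect_identical(dec$spra, fr$spra)
  expect_identical(dec$sprb, fr$sprb)
  expect_identical(dec$diagnostics$n_frames, n)

  # the header pair never occurs inside a legal payload
  x <- as.integer(octets)
  hits <- which(x[-length(x)] == 0xAA & x[-1] == 0x55)
  expect_identical(hits, seq(1L, by = 10L, length.out = n))
})

test_that("a corrupted frame is skipped and the stream resynchronizes", {
  n <- 50L
  fr <- align_frames(rep(100L, n), rep(200L, n),
                     simulate_transport(spr_packetize(rep(300L, n), "A"),
                                        transport_spec()),
                     simulate_transport(spr_packetize(rep(400L, n), "B"),
                                        transport_spec()))
  octets <- as.integer(encode_frames(fr))
  octets[11] <- 0x00L                        # destroy the second frame header
  dec <- decode_frames(octets)
  expect_identical(dec$diagnostics$n_frames, n - 1L)
  expect_gt(dec$diagnostics$n_skipped_octets, 0L)
  expect_true(all(dec$ecg1 == 100L))
})

test_that("capture files round-trip through disk", {
  n <- 80L
  fr <- align_frames(0:(n - 1), rep(7L, n),
                     simulate_transport(spr_packetize(rep(9L, n), "A"),
                                        transport_spec()),
                     list())
  path <- tempfile(fileext = ".bin")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_capture(fr, path, config_hash = "cafe")
  dec <- read_capture(path)
  expect_identical(dec$ecg1, fr$ecg1)
  expect_identical(dec$spra, fr$spra)
  expect_identical(dec$fs_hz, 200)
})

test_that("stale fraction tracks the injected per-packet loss rate", {
  n_pkt <- 2000L
  loss <- 0.03
  codes <- rep.int(1000L, 8L * n_pkt)
  pk <- spr_packetize(codes, "A")
  del <- simulate_transport(pk, transport_spec(loss_prob = loss, seed = 9))
  fr <- align_frames(rep(0L, 8L * n_pkt), rep(0L, 8L * n_pkt), del, list())
  rep_ <- data_loss_report(fr)
  # per-sample stale fraction equals packet loss within 3 binomial sd
  se <- sqrt(loss * (1 - loss) / n_pkt)
  expect_lt(abs(rep_$stale_a / rep_$total_a - loss), 3 * se)
})
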