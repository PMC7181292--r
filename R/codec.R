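# Wire formats and transport.
#
# SPR sample coding (2 octets per 12-bit code): every octet carries 6 data
# bits plus two flag bits so the receiver can classify any octet in
# isolation. Normative layout for this artifact:
#   bit 7 : H/L flag (1 = high byte, carrying the 6 MSBs)
#   bit 6 : AB flag  (0 = box A, 1 = box B)
#   bits 5..0 : data slice
# A packet is 8 consecutive samples (40 ms at 200 Hz) = 16 octets, H byte
# first for each sample.
#
# ECG-box frame (10 octets every 5 ms): header 0xAA 0x55, ECG1 and ECG2 as
# big-endian 12-bit codes with the top 4 bits zero, then one encoded SPR
# sample per box (H, L). The header pair cannot occur inside a legal
# payload: ECG high octets are <= 0x0F, SPR H octets are >= 0x80 but the
# octet following any candidate 0xAA position is structurally != 0x55.

SPR_FLAG_H <- 0x80L
SPR_FLAG_B <- 0x40L
FRAME_HEADER <- c(0xAAL, 0x55L)
FRAME_LEN <- 10L

#' Encode one 12-bit SPR sample as two flagged octets
#'
#' @param code integer code(s) in `[0, 4095]` (vectorized).
#' @param box `"A"` or `"B"`.
#' @return integer matrix with columns `high`, `low` (one row per code).
#' @export
encode_spr_sample <- function(code, box = c("A", "B")) {
  box <- match.arg(box)
  code <- as.integer(code)
  if (any(code < 0 | code > 4095))
    stop("SPR code out of range [0, 4095]", call. = FALSE)
  ab <- if (box == "A") 0L else SPR_FLAG_B
  high <- bitwOr(bitwOr(SPR_FLAG_H, ab), bitwShiftR(code, 6L))
  low <- bitwOr(ab, bitwAnd(code, 0x3FL))
  cbind(high = high, low = low)
}

# classify one octet: list(h = is-high-byte, box = "A"/"B", data = 6 bits)
.spr_octet_info <- function(octet) {
  list(h = bitwAnd(octet, SPR_FLAG_H) != 0L,
       box = ifelse(bitwAnd(octet, SPR_FLAG_B) != 0L, "B", "A"),
       data = bitwAnd(octet, 0x3FL))
}

#' Decode a raw octet stream of SPR sample bytes
#'
#' Pairs high/low octets per box using the flag bits. Tolerant to missing
#' octets: an unexpected high byte flushes the pending one (counted as an
#' orphan) and resynchronizes; a low byte with no pending high byte is an
#' orphan too. Never raises on malformed input.
#'
#' @param octets integer vector of octet values (0-255).
#' @return list with `A` and `B` integer code vectors and `diagnostics`
#'   (`orphans` = count of unpaired octets).
#' @export
decode_spr_stream <- function(octets) {
  octets <- as.integer(octets)
  codes <- list(A = integer(), B = integer())
  pending <- list(A = NA_integer_, B = NA_integer_)
  orphans <- 0L
  info_h <- bitwAnd(octets, SPR_FLAG_H) != 0L
  info_b <- ifelse(bitwAnd(octets, SPR_FLAG_B) != 0L, "B", "A")
  info_d <- bitwAnd(octets, 0x3FL)
  # accumulate per box in pre-allocated buffers for speed
  buf <- list(A = integer(length(octets)), B = integer(length(octets)))
  nb <- c(A = 0L, B = 0L)
  for (i in seq_along(octets)) {
    bx <- info_b[i]
    if (info_h[i]) {
      if (!is.na(pending[[bx]])) orphans <- orphans + 1L
      pending[[bx]] <- info_d[i]
    } else {
      if (is.na(pending[[bx]])) {
        orphans <- orphans + 1L
      } else {
        nb[bx] <- nb[bx] + 1L
        buf[[bx]][nb[bx]] <- bitwOr(bitwShiftL(pending[[bx]], 6L), info_d[i])
        pending[[bx]] <- NA_integer_
      }
    }
  }
  for (bx in c("A", "B")) if (!is.na(pending[[bx]])) orphans <- orphans + 1L
  list(A = buf$A[seq_len(nb["A"])], B = buf$B[seq_len(nb["B"])],
       diagnostics = list(orphans = orphans))
}

#' Build 8-sample SPR packets from a code sequence
#'
#' Groups consecutive ADC codes into packets of eight (40 ms of data at
#' 200 Hz); a trailing partial group is dropped. Each packet records its
#' send time: the packet leaves the box after its last sample has been
#' acquired, i.e. at `t0 + 8 * (p + 1) * Ts` for packet index `p`.
#'
#' @param codes integer vector of 12-bit ADC codes.
#' @param box `"A"` or `"B"`.
#' @param fs_hz sampling rate (default 200).
#' @param t0_s acquisition start time.
#' @return list of packets; each is `list(box, samples, send_time_s)`.
#' @export
spr_packetize <- function(codes, box = c("A", "B"), fs_hz = 200, t0_s = 0) {
  box <- match.arg(box)
  np <- length(codes) %/% 8L
  lapply(seq_len(np), function(p) {
    list(box = box,
         samples = as.integer(codes[(8L * (p - 1L) + 1L):(8L * p)]),
         send_time_s = t0_s + 8 * p / fs_hz)
  })
}

#' Serialize one SPR packet to its 16 wire octets
#' @param packet a packet from [spr_packetize()].
#' @return integer vector of 16 octet values.
#' @export
spr_packet_octets <- function(packet) {
  m <- encode_spr_sample(packet$samples, packet$box)
  as.integer(t(m))  # H, L per sample
}

#' Transport specification
#'
#' A one-hop UDP-like link: constant mean latency, bounded uniform jitter
#' and Bernoulli packet loss. Jitter is capped below the packet period so no
#' reordering can occur.
#'
#' @param packet_period_s nominal packet cadence (default 40 ms).
#' @param latency_s mean one-way latency (>= 0).
#' @param latency_jitter_s half-width of the uniform jitter (>= 0; must be
#'   below `packet_period_s / 2`).
#' @param loss_prob per-packet Bernoulli loss probability in `[0, 1]`.
#' @param seed integer seed (mandatory when the transport is stochastic).
#' @return An object of class `transport_spec`.
#' @export
transport_spec <- function(packet_period_s = 0.040, latency_s = 0,
                           latency_jitter_s = 0, loss_prob = 0, seed = NULL) {
  if (latency_s < 0 || latency_jitter_s < 0)
    stop("latencies must be >= 0", call. = FALSE)
  if (loss_prob < 0 || loss_prob > 1)
    stop("`loss_prob` must be in [0, 1]", call. = FALSE)
  if (latency_jitter_s >= packet_period_s / 2)
    stop("jitter must stay below half the packet period (no reordering)",
         call. = FALSE)
  if (is.null(seed) && (loss_prob > 0 || latency_jitter_s > 0))
    stop("`seed` is mandatory for a stochastic transport", call. = FALSE)
  structure(list(packet_period_s = packet_period_s, latency_s = latency_s,
                 latency_jitter_s = latency_jitter_s, loss_prob = loss_prob,
                 seed = seed),
            class = "transport_spec")
}

#' Simulate packet transport
#'
#' Each packet is dropped with probability `loss_prob`, otherwise delivered
#' at `send_time + latency + U(-jitter, +jitter)`. Deliveries keep send
#' order (jitter is bounded below the period). Bit-reproducible for a fixed
#' seed.
#'
#' @param packets list of packets from [spr_packetize()].
#' @param spec a [transport_spec].
#' @return list of delivered packets, each with an added `delivery_time_s`;
#'   attribute `n_lost` counts drops.
#' @export
simulate_transport <- function(packets, spec) {
  stopifnot(inherits(spec, "transport_spec"))
  n <- length(packets)
  if (n == 0) return(structure(list(), n_lost = 0L))
  draw <- function() {
    list(lost = stats::runif(n) < spec$loss_prob,
         jit = if (spec$latency_jitter_s > 0)
           stats::runif(n, -spec$latency_jitter_s, spec$latency_jitter_s)
         else numeric(n))
  }
  rnd <- if (!is.null(spec$seed)) with_seed(spec$seed, draw()) else draw()
  out <- vector("list", n)
  kept <- 0L
  for (i in seq_len(n)) {
    if (rnd$lost[i]) next
    kept <- kept + 1L
    pk <- packets[[i]]
    pk$delivery_time_s <- pk$send_time_s + spec$latency_s + rnd$jit[i]
    out[[kept]] <- pk
  }
  structure(out[seq_len(kept)], n_lost = sum(rnd$lost))
}

#' Align SPR deliveries with the ECG sample stream into 5 ms frames
#'
#' Every ECG sample period one frame is emitted carrying the current ECG
#' codes plus one SPR code per box popped from that box's FIFO (packets are
#' pushed into the FIFO on delivery). On FIFO underrun - before the first
#' packet arrives, or after a lost/late packet - the last emitted SPR code
#' is re-emitted (the configured idle code before anything was received)
#' and flagged stale.
#'
#' @param ecg1,ecg2 `adc_reading`s (or integer code vectors) at the frame
#'   cadence.
#' @param deliveries_a,deliveries_b delivered packet lists from
#'   [simulate_transport()].
#' @param fs_hz frame cadence (default 200 Hz).
#' @param t0_s time of the first frame.
#' @param idle_code SPR code emitted before any packet has arrived
#'   (default 2048, midscale).
#' @return An object of class `frame_set`: integer matrices are avoided in
#'   favor of parallel vectors `ecg1, ecg2, spra, sprb`, logical
#'   `stale_a, stale_b`, plus `fs_hz`, `t0_s`.
#' @export
align_frames <- function(ecg1, ecg2, deliveries_a, deliveries_b,
                         fs_hz = 200, t0_s = 0, idle_code = 2048L) {
  c1 <- if (inherits(ecg1, "adc_reading")) ecg1$codes else as.integer(ecg1)
  c2 <- if (inherits(ecg2, "adc_reading")) ecg2$codes else as.integer(ecg2)
  n <- min(length(c1), length(c2))
  pop_stream <- function(deliveries) {
    # returns codes + stale flags for n frames
    times <- vapply(deliveries, `[[`, numeric(1), "delivery_time_s")
    ord <- order(times)
    deliveries <- deliveries[ord]
    times <- times[ord]
    codes <- integer(n)
    stale <- logical(n)
    fifo <- integer(0)
    last <- as.integer(idle_code)
    di <- 1L
    for (k in seq_len(n)) {
      t_frame <- t0_s + (k - 1L) / fs_hz
      while (di <= length(deliveries) && times[di] <= t_frame) {
        fifo <- c(fifo, deliveries[[di]]$samples)
        di <- di + 1L
      }
      if (length(fifo)) {
        last <- fifo[1L]
        fifo <- fifo[-1L]
      } else {
        stale[k] <- TRUE
      }
      codes[k] <- last
    }
    list(codes = codes, stale = stale)
  }
  a <- pop_stream(deliveries_a)
  b <- pop_stream(deliveries_b)
  structure(list(ecg1 = c1[seq_len(n)], ecg2 = c2[seq_len(n)],
                 spra = a$codes, sprb = b$codes,
                 stale_a = a$stale, stale_b = b$stale,
                 fs_hz = fs_hz, t0_s = t0_s),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames @ %g Hz (%.2f s)\n",
              length(x$ecg1), x$fs_hz, length(x$ecg1) / x$fs_hz))
  cat(sprintf("  stale SPR samples: A %d, B %d\n",
              sum(x$stale_a), sum(x$stale_b)))
  invisible(x)
}

#' Serialize a frame set to wire octets
#'
#' 10 octets per frame: `0xAA 0x55`, ECG1 (big-endian, top 4 bits zero),
#' ECG2, SPR A (H, L), SPR B (H, L). 2000 octets per second at the 5 ms
#' cadence.
#'
#' @param frames a `frame_set` from [align_frames()].
#' @return a raw vector.
#' @export
encode_frames <- function(frames) {
  stopifnot(inherits(frames, "frame_set"))
  n <- length(frames$ecg1)
  ma <- encode_spr_sample(frames$spra, "A")
  mb <- encode_spr_sample(frames$sprb, "B")
  m <- rbind(FRAME_HEADER[1], FRAME_HEADER[2],
             bitwShiftR(frames$ecg1, 8L), bitwAnd(frames$ecg1, 0xFFL),
             bitwShiftR(frames$ecg2, 8L), bitwAnd(frames$ecg2, 0xFFL),
             ma[, "high"], ma[, "low"], mb[, "high"], mb[, "low"])
  as.raw(as.integer(m))
}

#' Decode a wire octet stream back into the four channel code streams
#'
#' Scans for the frame header, validates the structural octet constraints
#' (ECG high nibbles zero, SPR flag bits) and yields the four 200 Hz code
#' streams. A corrupted frame is skipped (scan resumes at the next header
#' candidate) and counted; decoding a stream produced by [encode_frames()]
#' is an exact inverse.
#'
#' @param octets a raw vector (or integer octet values).
#' @param fs_hz frame cadence.
#' @param t0_s time of the first frame.
#' @return list with integer code vectors `ecg1, ecg2, spra, sprb` and
#'   `diagnostics` (`n_frames`, `n_skipped_octets`).
#' @export
decode_frames <- function(octets, fs_hz = 200, t0_s = 0) {
  x <- as.integer(octets)
  n <- length(x)
  ecg1 <- ecg2 <- spra <- sprb <- integer(n %/% FRAME_LEN + 1L)
  nf <- 0L
  skipped <- 0L
  i <- 1L
  valid_frame <- function(fr) {
    fr[1] == FRAME_HEADER[1] && fr[2] == FRAME_HEADER[2] &&
      fr[3] <= 0x0FL && fr[5] <= 0x0FL &&
      bitwAnd(fr[7], 0xC0L) == SPR_FLAG_H &&
      bitwAnd(fr[8], 0xC0L) == 0x00L &&
      bitwAnd(fr[9], 0xC0L) == bitwOr(SPR_FLAG_H, SPR_FLAG_B) &&
      bitwAnd(fr[10], 0xC0L) == SPR_FLAG_B
  }
  while (i + FRAME_LEN - 1L <= n) {
    if (x[i] == FRAME_HEADER[1] && x[i + 1L] == FRAME_HEADER[2]) {
      fr <- x[i:(i + FRAME_LEN - 1L)]
      if (valid_frame(fr)) {
        nf <- nf + 1L
        ecg1[nf] <- bitwOr(bitwShiftL(fr[3], 8L), fr[4])
        ecg2[nf] <- bitwOr(bitwShiftL(fr[5], 8L), fr[6])
        spra[nf] <- bitwOr(bitwShiftL(bitwAnd(fr[7], 0x3FL), 6L),
                           bitwAnd(fr[8], 0x3FL))
        sprb[nf] <- bitwOr(bitwShiftL(bitwAnd(fr[9], 0x3FL), 6L),
                           bitwAnd(fr[10], 0x3FL))
        i <- i + FRAME_LEN
        next
      }
    }
    skipped <- skipped + 1L
    i <- i + 1L
  }
  idx <- seq_len(nf)
  list(ecg1 = ecg1[idx], ecg2 = ecg2[idx], spra = spra[idx], sprb = sprb[idx],
       fs_hz = fs_hz, t0_s = t0_s,
       diagnostics = list(n_frames = nf,
                          n_skipped_octets = skipped + (n - i + 1L)))
}

#' Write / read a binary frame capture
#'
#' The capture file is the raw concatenated 10-octet frames; a JSON sidecar
#' (`<path>.json`) stores the start time, frame rate and a configuration
#' hash so a capture can be decoded without its session.
#'
#' @param frames a `frame_set`.
#' @param path output file.
#' @param config_hash optional string identifying the generating
#'   configuration.
#' @return `path`, invisibly.
#' @export
write_capture <- function(frames, path, config_hash = NULL) {
  writeBin(encode_frames(frames), path)
  jsonlite::write_json(
    list(fs_hz = frames$fs_hz, t0_s = frames$t0_s,
         n_frames = length(frames$ecg1), config_hash = config_hash),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_capture
#' @export
read_capture <- function(path) {
  octets <- readBin(path, what = "raw", n = file.size(path))
  side <- paste0(path, ".json")
  fs <- 200; t0 <- 0
  if (file.exists(side)) {
    info <- jsonlite::read_json(side)
    if (!is.null(info$fs_hz)) fs <- as.numeric(info$fs_hz)
    if (!is.null(info$t0_s)) t0 <- as.numeric(info$t0_s)
  }
  decode_frames(octets, fs_hz = fs, t0_s = t0)
}

#' Stale-sample / data-loss statistics of a frame set
#'
#' @param frames a `frame_set` (or anything with logical `stale_a`,
#'   `stale_b`).
#' @param skip_cold_start drop the leading all-stale run (frames emitted
#'   before the first packet arrived) before counting; default `TRUE`.
#' @return list with per-box and pooled stale counts, totals, fractions and
#'   the mean gap (in seconds) between stale events.
#' @export
data_loss_report <- function(frames, skip_cold_start = TRUE) {
  strip <- function(st) {
    if (skip_cold_start && length(st)) {
      first_ok <- match(FALSE, st)
      if (is.na(first_ok)) return(logical(0))
      st <- st[first_ok:length(st)]
    }
    st
  }
  sa <- strip(frames$stale_a)
  sb <- strip(frames$stale_b)
  fs <- frames$fs_hz
  gap <- function(st) {
    w <- which(st)
    if (length(w) < 2) return(NA_real_)
    mean(diff(w)) / fs
  }
  tot <- length(sa) + length(sb)
  list(stale_a = sum(sa), stale_b = sum(sb),
       total_a = length(sa), total_b = length(sb),
       stale = sum(sa) + sum(sb), total = tot,
       fraction = if (tot > 0) (sum(sa) + sum(sb)) / tot else NA_real_,
       mean_gap_s = mean(c(gap(sa), gap(sb)), na.rm = TRUE))
}
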