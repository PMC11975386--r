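#' Write a trajectory in XYZ format
#'
#' One frame per stored configuration, coordinates in nm. The element tag
#' encodes the bead role: `C` chain spacer, `S` chain sticker, `O` cargo
#' spacer, `N` cargo sticker. A comment line carries the frame index and a
#' final trailer comment (`frames=<n>`) makes truncation detectable.
#'
#' @param frames List of chain-bead position matrices (sigma units), e.g.
#'   the `frames` attribute of [run_bd()]; cargo beads are appended when the
#'   system has a cargo and `cargo_traj` rows are supplied.
#' @param system The `npc_system` the frames belong to.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, system, path) {
  stopifnot(inherits(system, "npc_system"))
  s <- system$units[["sigma_nm"]]
  elem <- ifelse(system$sticker, "S", "C")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    f <- frames[[i]] * s
    writeLines(as.character(nrow(f)), con)
    writeLines(sprintf("frame %d of %d (nm)", i, length(frames)), con)
    writeLines(sprintf("%s %.4f %.4f %.4f", elem, f[, 1], f[, 2], f[, 3]), con)
  }
  writeLines(c("0", sprintf("frames=%d", length(frames))), con)
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path File written by [write_trajectory()] (or any plain XYZ; the
#'   trailer check is skipped if absent, truncated frames always error).
#' @return List of frames; each a list with `elements` and `pos` (nm).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  n_declared <- NA_integer_
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected an atom count at line ", i)
    if (n == 0L) { # trailer record
      if (i + 1 <= length(lines) && grepl("^frames=", lines[i + 1]))
        n_declared <- as.integer(sub("frames=", "", lines[i + 1]))
      i <- i + 2L
      break
    }
    if (i + 1 + n > length(lines))
      stop("truncated XYZ frame at line ", i, ": expected ", n, " atoms")
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    frames[[length(frames) + 1L]] <- list(
      elements = vapply(parts, `[`, "", 1),
      pos = matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                   ncol = 3, byrow = TRUE))
    i <- i + 2L + n
  }
  if (!is.na(n_declared) && n_declared != length(frames))
    stop("corrupt trajectory trailer: declares ", n_declared,
         " frames, found ", length(frames))
  frames
}

#' Checkpoint a system to disk and restore it
#'
#' Checkpoints carry the complete state — positions, sticker states and
#' binding registry, cargo pose and the RNG state — so a restored run
#' continues bit-exactly. A trailer field guards against truncated files.
#'
#' @param system An `npc_system`.
#' @param path Checkpoint file.
#' @return `write_checkpoint()`: `path` invisibly; `read_checkpoint()`: the
#'   restored `npc_system`.
#' @export
write_checkpoint <- function(system, path) {
  stopifnot(inherits(system, "npc_system"))
  saveRDS(list(format = "npcflux-checkpoint", version = 1L,
               system = system, trailer = "complete"), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("unreadable checkpoint (truncated or not a checkpoint): ",
         conditionMessage(e)))
  if (!identical(obj$format, "npcflux-checkpoint") ||
      !identical(obj$trailer, "complete"))
    stop("corrupt checkpoint: missing trailer record")
  obj$system
}

#' Generate a reduced-scale test system
#'
#' Scales the standard configuration down for desk-scale experiments while
#' preserving the regime the theory assumes: chain length, chain count and
#' pore height scale linearly with `scale`, transverse dimensions (box and
#' pore diameter) with `sqrt(scale)`, which keeps the pore diameter below
#' the overlap diameter `D*` of the reduced chains. At `scale = 0.1` this
#' gives 8 chains of 21 beads in a 12 nm pore. A warning is issued if the
#' chosen scale breaks `D < D*`.
#'
#' @param scale Fraction of the full system (0 < scale <= 1).
#' @param seed Build seed (fixtures are deterministic in `scale` and
#'   `seed`).
#' @param cargo_d Optional cargo diameter, nm.
#' @param ... Further overrides forwarded to [npc_config()].
#' @return List with `config` (`npc_config`) and `system` (`npc_system`).
#' @export
generate_reduced_fixture <- function(scale = 0.1, seed = 1, cargo_d = NULL,
                                     ...) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  sl <- sqrt(scale)
  cfg <- npc_config(
    box = round(c(100, 100, 200) * sl),
    h = max(2, round(40 * scale)),
    D = max(4, floor(40 * sl)),
    N = max(5, round(209 * scale)),
    n_FG = max(4, round(80 * scale)),
    cargo_d = cargo_d,
    seed = seed,
    ...)
  p <- polymer_params(N = cfg$N, n_FG = cfg$n_FG, h = cfg$h)
  Dstar <- reference_scales(p)$D_star
  if (cfg$D >= Dstar)
    warning(sprintf(paste0("reduced system has D = %g nm >= D* = %.3g nm: ",
                           "below overlap concentration, outside the ",
                           "theory's regime"), cfg$D, Dstar))
  list(config = cfg, system = build_system(cfg, seed = seed))
}
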