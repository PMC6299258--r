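# The standard tract set: 16 white-matter tracts, 13 bilateral, grouped by
# category. Mirrors the usual neonatal virtual-dissection inventory.
tract_table <- function() {
  data.frame(
    name = c("cst", "ar", "atr", "str", "ptr",
             "slf", "ilf", "ifo", "unc",
             "fmi", "fma",
             "mcp", "ml",
             "fx", "cgc", "cgh"),
    long_name = c("corticospinal tract", "acoustic radiation",
                  "anterior thalamic radiation",
                  "superior thalamic radiation",
                  "posterior thalamic radiation",
                  "superior longitudinal fasciculus",
                  "inferior longitudinal fasciculus",
                  "inferior fronto-occipital fasciculus",
                  "uncinate fasciculus",
                  "forceps minor", "forceps major",
                  "middle cerebellar peduncle", "medial lemniscus",
                  "fornix", "cingulate gyrus part of the cingulum",
                  "parahippocampal part of the cingulum"),
    category = c(rep("projection", 5), rep("association", 4),
                 rep("callosal", 2), rep("cerebellar", 2),
                 rep("limbic", 3)),
    bilateral = c(rep(TRUE, 5), rep(TRUE, 4), FALSE, FALSE,
                  FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Write the default tract protocol library
#'
#' Materialises a synthetic stand-in for the standard-space tractography
#' protocol set: 16 tracts (13 bilateral) with seed, waypoint, stop and
#' exclusion masks defined as simple regions on a template grid, plus one
#' JSON descriptor per tract. The mask geometry is synthetic (boxes placed
#' per tract within each hemisphere, mirrored for bilateral tracts;
#' exclusion always contains the mid-sagittal plane except for the
#' commissural/brainstem-crossing tracts), intended for testing the
#' protocol-driven machinery, not as anatomical reference.
#'
#' @param dir output directory (created if needed).
#' @param shape template grid size (default c(32, 32, 20)).
#' @param voxel template voxel size in mm.
#' @return Invisibly, the directory path.
#' @export
write_default_protocols <- function(dir, shape = c(32, 32, 20),
                                    voxel = 1.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tt <- tract_table()
  affine <- diag(c(rep(voxel, 3), 1))
  affine[1:3, 4] <- -(shape - 1) / 2 * voxel
  cx <- round(shape[1] / 2)
  midsag <- array(FALSE, shape)
  midsag[cx, , ] <- TRUE
  box <- function(xr, yr, zr) {
    m <- array(FALSE, shape)
    xr <- pmin(pmax(xr, 1), shape[1])
    yr <- pmin(pmax(yr, 1), shape[2])
    zr <- pmin(pmax(zr, 1), shape[3])
    m[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- TRUE
    m
  }
  mirror_x <- function(m) m[rev(seq_len(dim(m)[1])), , , drop = FALSE]
  no_midsag <- c("fmi", "fma", "mcp")
  ny <- shape[2]; nz <- shape[3]
  for (i in seq_len(nrow(tt))) {
    nm <- tt$name[i]
    # each tract runs along y in a lane whose z-band differs per tract;
    # hemispheric tracts live in the x > centre half ("left")
    zlev <- 3 + ((i - 1) %% (nz - 8))
    seed_l <- box(c(cx + 3, cx + 6), c(4, 6), c(zlev, zlev + 2))
    way_l <- box(c(cx + 3, cx + 6), c(round(ny / 2) - 1, round(ny / 2) + 1),
                 c(zlev, zlev + 2))
    stop_l <- box(c(cx + 3, cx + 6), c(ny - 5, ny - 3), c(zlev, zlev + 2))
    excl <- midsag
    if (nm %in% no_midsag) {
      # commissural: seed spans the midline, no mid-sagittal exclusion
      seed_l <- box(c(cx - 2, cx + 2), c(4, 6), c(zlev, zlev + 2))
      way_l <- box(c(cx - 2, cx + 2), c(round(ny / 2) - 1,
                                        round(ny / 2) + 1),
                   c(zlev, zlev + 2))
      stop_l <- box(c(cx - 2, cx + 2), c(ny - 5, ny - 3),
                    c(zlev, zlev + 2))
      excl <- array(FALSE, shape)
    }
    desc <- list(name = nm, long_name = tt$long_name[i],
                 category = tt$category[i], bilateral = tt$bilateral[i])
    write_set <- function(suffix, seed, way, stp, exc) {
      fn <- function(role) sprintf("%s%s_%s.nii.gz", nm, suffix, role)
      write_volume(seed * 1, affine, file.path(dir, fn("seed")))
      write_volume(way * 1, affine, file.path(dir, fn("waypoint")))
      write_volume(stp * 1, affine, file.path(dir, fn("stop")))
      write_volume(exc * 1, affine, file.path(dir, fn("exclusion")))
      list(seed = fn("seed"), waypoint = list(fn("waypoint")),
           stop = fn("stop"), exclusion = fn("exclusion"))
    }
    if (tt$bilateral[i]) {
      desc$left <- write_set("_l", seed_l, way_l, stop_l, excl)
      desc$right <- write_set("_r", mirror_x(seed_l), mirror_x(way_l),
                              mirror_x(stop_l), excl)
    } else {
      desc$masks <- write_set("", seed_l, way_l, stop_l, excl)
    }
    jsonlite::write_json(desc, file.path(dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

read_mask_file <- function(dir, fn, tract) {
  path <- file.path(dir, fn)
  if (!file.exists(path))
    stop("missing mask file for tract '", tract, "': ", fn)
  v <- read_volume(path)
  list(data = v$data > 0.5, affine = v$affine)
}

load_mask_set <- function(dir, set, tract) {
  seed <- read_mask_file(dir, set$seed, tract)
  way <- lapply(unlist(set$waypoint), function(f)
    read_mask_file(dir, f, tract)$data)
  stp <- read_mask_file(dir, set$stop, tract)$data
  exc <- read_mask_file(dir, set$exclusion, tract)$data
  if (!sum(seed$data))
    stop("tract '", tract, "' has an empty seed mask")
  dims <- c(list(dim(seed$data), dim(stp), dim(exc)), lapply(way, dim))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("tract '", tract, "' has masks on incompatible grids")
  list(seed = seed$data, waypoint = way, stop = stp, exclusion = exc,
       affine = seed$affine)
}

#' Load tract protocols from a protocol directory
#'
#' Reads every JSON descriptor in the directory together with its mask
#' volumes. Bilateral protocols carry separate left/right mask sets.
#'
#' @param protocol_dir directory written by [write_default_protocols()]
#'   or following the same layout.
#' @return list of `tract_protocol` objects, each with fields `name`,
#'   `bilateral`, `category` and either `masks` or `left`/`right` mask
#'   sets (logical arrays seed / waypoint (list) / stop / exclusion).
#' @export
load_protocols <- function(protocol_dir) {
  files <- sort(list.files(protocol_dir, pattern = "\\.json$",
                           full.names = TRUE))
  if (!length(files)) stop("no protocol descriptors in ", protocol_dir)
  lapply(files, function(f) {
    desc <- jsonlite::read_json(f, simplifyVector = TRUE)
    out <- list(name = desc$name, long_name = desc$long_name,
                category = desc$category,
                bilateral = isTRUE(desc$bilateral))
    if (out$bilateral) {
      out$left <- load_mask_set(protocol_dir, desc$left, desc$name)
      out$right <- load_mask_set(protocol_dir, desc$right, desc$name)
    } else {
      out$masks <- load_mask_set(protocol_dir, desc$masks, desc$name)
    }
    structure(out, class = "tract_protocol")
  })
}

#' @export
print.tract_protocol <- function(x, ...) {
  cat("tract_protocol:", x$name,
      if (x$bilateral) "(bilateral)" else "", "\n")
  invisible(x)
}

#' Build a tract protocol in code
#'
#' @param name tract name.
#' @param seed,stop,exclusion logical 3-D arrays.
#' @param waypoint list of logical 3-D arrays (may be empty).
#' @param bilateral logical flag (single-hemisphere object; bilateral
#'   pairs are built by supplying two protocols or a left/right set).
#' @return a `tract_protocol`.
#' @export
tract_protocol <- function(name, seed, waypoint = list(), stop = NULL,
                           exclusion = NULL, bilateral = FALSE) {
  if (!sum(seed)) stop("tract '", name, "' has an empty seed mask")
  d <- dim(seed)
  if (is.null(stop)) stop <- array(FALSE, d)
  if (is.null(exclusion)) exclusion <- array(FALSE, d)
  if (!is.list(waypoint)) waypoint <- list(waypoint)
  for (m in c(waypoint, list(stop, exclusion)))
    if (!all(dim(m) == d)) stop("masks on incompatible grids")
  structure(list(name = name, bilateral = bilateral,
                 masks = list(seed = seed, waypoint = waypoint,
                              stop = stop, exclusion = exclusion)),
            class = "tract_protocol")
}
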