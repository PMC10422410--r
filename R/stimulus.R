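# TMT stimulus layouts: circular AOIs, expected visiting sequences, and
# seeded random placement for the four stimuli.

STIMULUS_IDS <- c("tmt_a_simple", "tmt_a_complex", "tmt_b_simple",
                  "tmt_b_complex")

# Labels and the expected visiting order for each stimulus. TMT-A is an
# ascending number trail; TMT-B alternates numbers and letters in the
# standard 1-A-2-B-... order.
stimulus_sequence <- function(stimulus_id) {
  switch(stimulus_id,
    tmt_a_simple = as.character(1:8),
    tmt_a_complex = as.character(1:25),
    tmt_b_simple = as.vector(rbind(as.character(1:4), LETTERS[1:4])),
    tmt_b_complex = as.vector(rbind(as.character(1:12), LETTERS[1:12])),
    stop_param("unknown stimulus_id: ", stimulus_id)
  )
}

#' Generate a TMT stimulus layout
#'
#' Places the circular targets (AOIs) of one of the four TMT stimuli at
#' random non-overlapping positions on the canvas, by rejection sampling
#' with a minimum center separation, and records the expected visiting
#' sequence: ascending numbers for TMT-A, the alternating ascending
#' number-letter chain (1, A, 2, B, ...) for TMT-B.
#'
#' @param stimulus_id One of `"tmt_a_simple"` (targets 1-8),
#'   `"tmt_a_complex"` (1-25), `"tmt_b_simple"` (1-4 and A-D),
#'   `"tmt_b_complex"` (1-12 and A-L).
#' @param width,height Canvas size in pixels.
#' @param radius Target disc radius in pixels.
#' @param seed Integer seed; identical seeds give identical layouts.
#' @param min_sep_factor Minimum center separation as a multiple of
#'   `radius`.
#' @param max_retries Total rejection-sampling retries before a geometry
#'   error.
#' @return An object of class `etmt_layout`: list with `stimulus_id`,
#'   `width`, `height`, `aois` (data frame `label,cx,cy,radius`) and
#'   `expected_sequence`.
#' @export
make_layout <- function(stimulus_id, width = 1280, height = 720,
                        radius = 40, seed = 1L, min_sep_factor = 2.5,
                        max_retries = 10000L) {
  if (length(stimulus_id) != 1L || !stimulus_id %in% STIMULUS_IDS) {
    stop_param("unknown stimulus_id: ", paste(stimulus_id, collapse = ", "),
               " (expected one of ", paste(STIMULUS_IDS, collapse = ", "),
               ")")
  }
  sequence <- stimulus_sequence(stimulus_id)
  labels <- sequence # every target appears exactly once in the trail
  n <- length(labels)
  if (width < 4 * radius || height < 4 * radius) {
    stop_param("canvas too small for radius ", radius)
  }
  min_sep <- min_sep_factor * radius
  cx <- numeric(n); cy <- numeric(n)
  with_seed(seed, {
    tries <- 0L
    for (i in seq_len(n)) {
      repeat {
        tries <- tries + 1L
        if (tries > max_retries) {
          stop_param("could not place ", n, " AOIs after ", max_retries,
                     " retries; enlarge the canvas or shrink the radius")
        }
        px <- stats::runif(1, radius, width - radius)
        py <- stats::runif(1, radius, height - radius)
        if (i == 1L ||
            all(sqrt((cx[seq_len(i - 1L)] - px)^2 +
                       (cy[seq_len(i - 1L)] - py)^2) >= min_sep)) {
          cx[i] <- px; cy[i] <- py
          break
        }
      }
    }
  })
  structure(list(stimulus_id = stimulus_id, width = width, height = height,
                 aois = data.frame(label = labels, cx = cx, cy = cy,
                                   radius = radius,
                                   stringsAsFactors = FALSE),
                 expected_sequence = sequence),
            class = "etmt_layout")
}

#' @export
print.etmt_layout <- function(x, ...) {
  cat(sprintf("<etmt_layout> %s: %d AOIs on %dx%d px, trail %s ... %s\n",
              x$stimulus_id, nrow(x$aois), x$width, x$height,
              x$expected_sequence[1],
              x$expected_sequence[length(x$expected_sequence)]))
  invisible(x)
}

#' Which AOI contains a point?
#'
#' Returns the label of the AOI disc containing `(x, y)`, or `NA` if none.
#' A point exactly on the boundary circle counts as inside.
#'
#' @param layout An [make_layout()] layout.
#' @param x,y Point in pixels.
#' @return AOI label (character) or `NA_character_`.
#' @export
aoi_hit <- function(layout, x, y) {
  a <- layout$aois
  d2 <- (a$cx - x)^2 + (a$cy - y)^2
  hit <- which(d2 <= a$radius^2)
  if (!length(hit)) return(NA_character_)
  a$label[hit[which.min(d2[hit])]]
}

#' Write or read a stimulus layout as JSON
#'
#' @param layout An `etmt_layout`.
#' @param path File path.
#' @return `read_layout` returns the layout; `write_layout` returns `path`
#'   invisibly.
#' @export
write_layout <- function(layout, path) {
  payload <- list(stimulus_id = layout$stimulus_id, width = layout$width,
                  height = layout$height,
                  aois = lapply(seq_len(nrow(layout$aois)), function(i) {
                    as.list(layout$aois[i, , drop = FALSE])
                  }),
                  expected_sequence = as.list(layout$expected_sequence))
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  p <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                          simplifyVector = FALSE)
  aois <- do.call(rbind, lapply(p$aois, function(a) {
    data.frame(label = a$label, cx = a$cx, cy = a$cy, radius = a$radius,
               stringsAsFactors = FALSE)
  }))
  structure(list(stimulus_id = p$stimulus_id, width = p$width,
                 height = p$height, aois = aois,
                 expected_sequence = unlist(p$expected_sequence)),
            class = "etmt_layout")
}

#' Generate the full set of four TMT layouts
#'
#' @param seed Integer seed; each stimulus gets a derived child seed.
#' @param ... Passed to [make_layout()].
#' @return Named list of layouts keyed by stimulus id.
#' @export
make_layout_set <- function(seed = 1L, ...) {
  seeds <- derive_seeds(seed, length(STIMULUS_IDS))
  layouts <- Map(function(id, s) make_layout(id, seed = s, ...),
                 STIMULUS_IDS, seeds)
  names(layouts) <- STIMULUS_IDS
  layouts
}
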