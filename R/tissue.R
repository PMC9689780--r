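#' Default 16-tissue dielectric property table at 300 MHz
#'
#' The nested-tissue head model distinguishes 16 tissue classes, ordered from
#' the outermost shell (skin) to the innermost core. Each entry carries the
#' relative permittivity `eps_r` and conductivity `sigma` (S/m) at the
#' 300 MHz operating frequency. The values are literature-plausible for head
#' tissues in the VHF band; they are defaults, not measurements, and any
#' 16-row table with valid physics may be substituted via [tissue_table()].
#'
#' The ceiling of the table (cerebrospinal fluid, eps_r = 72) is chosen so
#' that even after the strategy's maximum 1.2x property scaling every normal
#' tissue stays below the anomalous-scatterer permittivity menu (90, 120,
#' 150), keeping lesion-like inclusions separable by threshold.
#'
#' @param frequency_hz Operating frequency the table is valid for.
#' @return A `braintomo_tissues` tibble with columns `tissue`, `eps_r`,
#'   `sigma`, and attribute `frequency_hz`.
#' @examples
#' default_tissue_table()
#' @export
default_tissue_table <- function(frequency_hz = 3e8) {
  tb <- tibble::tribble(
    ~tissue,            ~eps_r, ~sigma,
    "skin",               49.0,   0.64,
    "fat",                 5.6,   0.10,
    "muscle",             58.0,   0.77,
    "skull_cortical",     13.0,   0.12,
    "skull_cancellous",   21.0,   0.24,
    "dura",               44.0,   0.83,
    "csf",                72.0,   2.22,
    "grey_matter",        60.0,   0.69,
    "white_matter",       43.8,   0.45,
    "blood_pool",         65.7,   1.58,
    "cerebellum",         49.4,   0.79,
    "corpus_callosum",    38.0,   0.41,
    "thalamus",           55.0,   0.72,
    "hypothalamus",       56.0,   0.74,
    "midbrain",           45.0,   0.58,
    "brainstem",          40.0,   0.48
  )
  tissue_table(tb, frequency_hz = frequency_hz)
}

#' Construct and validate a tissue property table
#'
#' @param entries Data frame with columns `tissue`, `eps_r`, `sigma`, ordered
#'   outermost to innermost.
#' @param frequency_hz Frequency (Hz) at which the properties hold.
#' @return A validated `braintomo_tissues` tibble.
#' @export
tissue_table <- function(entries, frequency_hz = 3e8) {
  tb <- tibble::as_tibble(entries)
  if (!all(c("tissue", "eps_r", "sigma") %in% names(tb)))
    abort("tissue table needs columns: tissue, eps_r, sigma")
  if (anyDuplicated(tb$tissue))
    abort("tissue names must be unique")
  if (any(tb$eps_r < 1))
    abort("all eps_r must be >= 1")
  if (any(tb$sigma < 0))
    abort("all sigma must be >= 0")
  attr(tb, "frequency_hz") <- frequency_hz
  class(tb) <- c("braintomo_tissues", class(tb))
  tb
}

#' Subset a tissue table to fewer, representative layers
#'
#' Coarse grids cannot rasterize 16 thin nested shells; desk-scale toy
#' datasets use a reduced stack (default 3 layers spanning the property
#' range: skin-like, fluid-like, cortex-like) while keeping the same
#' nested-tissue topology.
#'
#' @param table A full tissue table.
#' @param n Number of layers to keep.
#' @return A `braintomo_tissues` tibble with `n` rows.
#' @export
subset_tissue_table <- function(table = default_tissue_table(), n = 3) {
  stopifnot(n >= 1, n <= nrow(table))
  if (n == 3 && nrow(table) == 16) {
    idx <- c(1L, 7L, 8L) # skin, csf, grey matter: wide eps/sigma spread
  } else {
    idx <- unique(round(seq(1, nrow(table), length.out = n)))
  }
  tissue_table(table[idx, ], frequency_hz = attr(table, "frequency_hz"))
}
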