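# Shared fixtures, generated in code. The default phantom is built once
# per test run and reused read-only across files.

vm_cache <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(vm_cache$phantom)) {
    vm_cache$phantom <- make_phantom(phantom_spec())
  }
  vm_cache$phantom
}

# mark an identity-pose phantom's label volume as ACPC-aligned
aligned_from <- function(phantom) {
  ventmorph:::as_acpc_volume(phantom$labels, phantom$spec$acpc_mm)
}

# hand-built label volume in the canonical frame: a brain box with a
# ventricle box carved out, dimensions in voxels at 1 mm
tiny_brain <- function(vent_x = 11:20, vent_y = 11:20, vent_z = 11:20,
                       dims = c(31, 41, 31), origin = c(-15.5, -25.5, -15.5),
                       acpc_mm = 15) {
  arr <- array(1L, dims)
  arr[vent_x, vent_y, vent_z] <- 2L
  vol <- label_volume(arr, c(1, 1, 1), origin)
  ventmorph:::as_acpc_volume(vol, acpc_mm)
}

# complete mFI-11 record as a one-row tibble, all items FALSE except `on`
mfi_record <- function(on = character()) {
  items <- mfi11_items()
  rec <- as.list(stats::setNames(items %in% on, items))
  tibble::as_tibble(rec)
}
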