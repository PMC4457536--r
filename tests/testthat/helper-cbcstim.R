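# Shared fixtures: cells are cheap to build; the standard field solve is
# memoised so the whole suite pays for it once.

.fixtures <- new.env(parent = emptyenv())

std_field <- function() {
  if (is.null(.fixtures$field))
    .fixtures$field <- solve_potential(volume_model(), electrode_spec(),
                                       drive = 1, grid_spacing = 10)
  .fixtures$field
}

on_cell <- function() {
  if (is.null(.fixtures$on)) .fixtures$on <- build_cell(on_spec())
  .fixtures$on
}

off_cell <- function() {
  if (is.null(.fixtures$off)) .fixtures$off <- build_cell(off_spec())
  .fixtures$off
}

# minimal SWC fixtures written on the fly
write_tmp_swc <- function(lines) {
  path <- tempfile(fileext = ".swc")
  writeLines(lines, path)
  path
}

single_soma_swc <- function() write_tmp_swc("1 1 0 0 5.5 5.5 -1")

two_comp_swc <- function() write_tmp_swc(c(
  "1 1 0 0 0 5.5 -1",
  "2 2 0 0 15.5 0.6 1"))
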