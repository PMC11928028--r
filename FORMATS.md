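# File formats

All text formats use `#`-prefixed comment headers for metadata and plain CSV
bodies; JSON files are written with `jsonlite` at full double precision.

## ThT trace CSV (`write_trace_csv` / `read_trace_csv`)

```
# label: <free text>
# normalized: TRUE|FALSE
# dynamic_range: <max/min of the raw fluorescence, optional>
# <extra key>: <value>          (e.g. variant, seed, irradiance)
# package: biofilmwave <version>
time_min,intensity
0,0.0132...
```

`time_min` strictly increasing (minutes); `intensity` non-negative
fluorescence (arbitrary units; [0, 1] when normalized). Write then read is
an identity to full float precision.

## FDF frames CSV (`write_frames_csv` / `read_frames_csv`)

Long format, one row per cell per frame:

```
# radius: <biofilm radius, um>
# spacing: <lattice spacing, um>
# package: biofilmwave <version>
t,cell_id,x,y,z,state,tht
```

`state` codes: 0 quiescent, 1 firing, 2 refractory, 3 habituated.
Positions in um, `t` in minutes, `tht` the per-cell fluorescence proxy.

## Wavefront track CSV (`write_track_csv` / `read_track_csv`)

```
# phase: centrifugal|centripetal
# source: <provenance>
# exclude_below: <um>
time_min,R_um
```

## Run configuration JSON (`load_config` / `save_config`)

Top-level keys: `seed` plus optional blocks `hh`, `fdf`, `template`,
`stimulus`. Block fields are exactly the constructor arguments of
`hh_params()`, `fdf_params()` and `trace_template()`; units are documented
on those help pages (minutes, mV, uW/mm^2, um). Unknown keys anywhere are
rejected; all violations are reported together. A complete example ships as
`inst/extdata/default_config.json`.

## Fit and statistics JSON

Wavefront fits: `{phase: {phase, Rc, b, gamma, Rc_sd, b_sd, gamma_sd,
n_points}}`. Peak calls: `{n_peaks, peak_times, peak_heights,
plateau_peak}`. Critical radius: `{mean, sd, estimates}`.

## Image stacks (`write_image_stack` / `read_image_stack`)

Multi-page 32-bit float TIFF; pages are z-slices, frame-major (all z of
frame 1, then frame 2, ...). Intensities are scaled to [0, 1] by a factor
recorded in a JSON sidecar `<path>.json` together with the array
dimensions, frame times (min) and voxel size (um), making the round trip
lossless in structure.
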