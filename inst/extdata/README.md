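# extdata drop-in

The per-bat supplementary tables of the original tracking study are not
redistributed with this package. To enable the full-fidelity re-analyses
(see `?supplementary_path`), place CSV conversions here:

- `daily_ranges.csv`: columns `bat_id,log_area,disturbance,day,moon,sex`
  (one row per bat-night; `log_area` is the natural log of the daily
  95% MCP area in m²).
- `used_available.csv`: columns `bat_id,category,used,available`
  (`used` = fix counts in the bat's focus areas, `available` = area
  fraction of the bat's availability circle; categories
  natural/degraded/farmland/pasture/urban).
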