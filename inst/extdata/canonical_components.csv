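# Canonical flash-evoked CSD components for a mouse V1-like column.
# Versioned defaults; depths in um below pia, times in ms after flash onset,
# amplitudes in arbitrary planar-CSD units (sinks negative, sources positive).
name,polarity,depth_center,depth_sigma,onset,duration,peak_amplitude,temporal_shape
l4_sink,sink,370,50,40,15,-1.0,transient
l4_source,source,370,60,60,190,0.6,sustained
l56_sink,sink,660,80,50,200,-0.45,sustained
l23_sink,sink,200,60,60,190,-0.5,sustained
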