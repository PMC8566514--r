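kind,mz_or_mass,label
neutral_loss,162.0528,anhydroglucose -162.0528
neutral_loss,18.010565,water -18.0106
neutral_loss,35.976678,hydrogen chloride -35.9767
neutral_loss,79.926162,hydrogen bromide -79.9262
neutral_loss,27.994915,carbon monoxide -27.9949
neutral_loss,27.010899,hydrogen cyanide -27.0109
neutral_loss,31.042199,methylamine -31.0422
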