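muscle,group,knee_flexion,knee_extension,ankle_flexion,ankle_extension,toes_flexion,toes_extension
gastrocnemius,flexor,1,0,1,0,0,0
soleus,flexor,0,0,1,0,0,0
plantaris,flexor,1,0,1,0,0,0
popliteus,flexor,1,0,0,0,0,0
tibialis_posterior,flexor,0,0,1,0,0,0
flexor_digitorum_longus,flexor,0,0,1,0,1,0
flexor_hallucis_longus,flexor,0,0,1,0,1,0
tibialis_anterior,extensor,0,0,0,1,0,0
extensor_digitorum_longus,extensor,0,0,0,1,0,1
extensor_hallucis_longus,extensor,0,0,0,1,0,1
peroneus_tertius,extensor,0,0,0,1,0,0
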