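<?xml version="1.0" encoding="UTF-8"?>
<PhysiCell_settings version="devel-version">
	<domain>
		<x_min>-250</x_min>
		<x_max>250</x_max>
		<y_min>-250</y_min>
		<y_max>250</y_max>
		<z_min>-10</z_min>
		<z_max>10</z_max>
		<dx>20</dx>
		<dy>20</dy>
		<dz>20</dz>
		<use_2D>true</use_2D>
	</domain>
	<overall>
		<max_time units="min">120</max_time>
		<dt_diffusion units="min">0.01</dt_diffusion>
		<dt_mechanics units="min">0.1</dt_mechanics>
		<dt_phenotype units="min">6</dt_phenotype>
	</overall>
	<microenvironment_setup>
		<variable name="oxygen" units="mmHg" ID="0">
			<physical_parameter_set>
				<diffusion_coefficient units="micron^2/min">100000.0</diffusion_coefficient>
				<decay_rate units="1/min">0.1</decay_rate>
			</physical_parameter_set>
			<initial_condition units="mmHg">38.0</initial_condition>
			<Dirichlet_boundary_condition units="mmHg" enabled="true">38.0</Dirichlet_boundary_condition>
		</variable>
	</microenvironment_setup>
	<cell_definitions>
		<cell_definition name="default" ID="0">
			<phenotype>
				<motility>
					<speed units="micron/min">20.0</speed>
					<persistence_time units="min">5.0</persistence_time>
					<migration_bias units="dimensionless">1.5</migration_bias>
				</motility>
			</phenotype>
		</cell_definition>
	</cell_definitions>
</PhysiCell_settings>
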